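# Fixture builders and independent oracles used across the suite. All
# fixtures are generated in code; nothing is read from disk.

# Analytic point cloud on a cylinder surface: uniform in axial position and
# angle on the lateral wall, plus flat end disks (as a segmented cilium has
# end faces) so projection-extreme points sit at the true ends.
cylinder_cloud <- function(n = 2000, length_nm = 2000, radius_nm = 80,
                           center = c(0, 0, 0), axis = c(1, 0, 0),
                           end_fraction = 0.08, seed = 1) {
  set.seed(seed)
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal frame (axis, e1, e2)
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  n_end <- round(end_fraction * n)
  n_lat <- n - 2 * n_end
  t_lat <- runif(n_lat, 0, length_nm)
  th_lat <- runif(n_lat, 0, 2 * pi)
  r_lat <- rep(radius_nm, n_lat)
  t_end <- c(rep(0, n_end), rep(length_nm, n_end))
  th_end <- runif(2 * n_end, 0, 2 * pi)
  r_end <- radius_nm * sqrt(runif(2 * n_end))
  t_all <- c(t_lat, t_end); th <- c(th_lat, th_end); r <- c(r_lat, r_end)
  pts <- outer(t_all, axis) + outer(r * cos(th), e1) + outer(r * sin(th), e2)
  sweep(pts, 2, center, "+")
}

# Minimal cilium_geometry built directly from a point cloud (bypasses
# rasterization) for point-level tests.
make_geometry <- function(points, apical, cilium_id = 1L, row = "tall") {
  ends <- estimate_axis_and_ends(points, apical)
  meas <- measure_cilium(points, ends$axis, ends$tip_nm, ends$taper_nm)
  proj <- as.vector(sweep(points, 2, ends$taper_nm) %*% ends$axis)
  basal <- points[proj <= quantile(proj, 0.10), , drop = FALSE]
  structure(list(cilium_id = cilium_id, row = row, surface_points = points,
                 axis = ends$axis, tip_nm = ends$tip_nm,
                 taper_nm = ends$taper_nm, height_nm = meas$height_nm,
                 diameter_nm = meas$diameter_nm,
                 base_centroid_nm = colMeans(basal)),
            class = "cilium_geometry")
}

# Brute-force kNN bead assignment oracle: all-pairs distances, majority of
# the k nearest, ties to the owner of the single nearest point, discard by
# the cutoff against the winner's nearest point.
oracle_project <- function(centroids, cloud, owners, k = 10, cutoff_nm = 100) {
  t(apply(as.matrix(centroids[, c("z_nm", "y_nm", "x_nm")]), 1, function(p) {
    d <- sqrt(colSums((t(cloud) - p)^2))
    nn <- order(d)[seq_len(k)]
    tab <- table(owners[nn])
    winners <- names(tab)[tab == max(tab)]
    win <- if (length(winners) == 1) winners else as.character(owners[nn[1]])
    dwin <- min(d[owners == win])
    c(cilium = as.numeric(win), distance = dwin,
      discarded = as.numeric(dwin > cutoff_nm))
  }))
}

# A small rasterized one-row phantom for volume-level tests.
small_phantom_spec <- function(..., seed = 1L) {
  defaults <- list(
    n_cilia_per_row = c(tall = 3L, middle = 0L, short = 0L),
    row_height_sd_nm = c(tall = 0, middle = 0, short = 0),
    n_decoy_beads = 0L,
    rng_seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(bundle_phantom_spec, args)
}

expect_close <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", actual, expected, tol))
}
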