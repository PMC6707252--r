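# Synthetic hair-bundle phantoms with ground truth.
#
# The phantom is a stated world, not a fitting device: three staircase rows
# of capped-cylinder stereocilia arranged along a V, with row mean heights
# 2.39 / 1.93 / 1.24 um and mean diameters 157 / 182 / 129 nm, rasterized on
# an anisotropic grid (default 10 x 10 nm in-plane, 15 nm milling step).
# Gold beads are drawn from an inhomogeneous Poisson intensity over each
# cilium's surface (by default 10x enriched in the top 300 nm), displaced
# radially outward by |N(offset_mean, offset_sd)|, and recorded bead-by-bead
# in a ground-truth table; decoy beads are rejection-sampled to lie beyond
# the discard cutoff from every surface.

#' Default bead intensity field: uniform with tip enrichment
#'
#' Returns beads per um^2 as a function of row, height fraction, sector and
#' cilium height; `base_rate` everywhere except within `top_nm` of the tip,
#' where the rate is `tip_factor * base_rate`.
#'
#' @param base_rate baseline intensity, beads/um^2
#' @param tip_factor enrichment factor near the tip
#' @param top_nm extent of the enriched apical zone, nm from the tip
#' @return function `(row, height_fraction, sector, height_nm) -> rate`
#' @export
tip_enriched_field <- function(base_rate = 50, tip_factor = 10, top_nm = 300) {
  force(base_rate); force(tip_factor); force(top_nm)
  function(row, height_fraction, sector, height_nm) {
    rate <- rep(base_rate, length(height_fraction))
    rate[height_nm * (1 - height_fraction) <= top_nm] <- base_rate * tip_factor
    rate
  }
}

#' Specification of a bundle phantom
#'
#' Defaults encode the measured bundle statistics: mean heights 2390 / 1930
#' / 1240 nm (SD 160 / 140 / 70), mean diameters 157 / 182 / 129 nm for the
#' tall / middle / short rows, a 90-degree V, and beads 10x enriched within
#' 300 nm of the tips. The bead offset distribution (|N(15, 5)| nm) is a
#' modeling choice for the antibody + gold linkage, which has no measured
#' value.
#'
#' @param n_cilia_per_row named integer, cilia per row
#' @param row_height_mean_nm,row_height_sd_nm named numeric per row, nm
#' @param row_diameter_nm named numeric per row, nm
#' @param inter_cilium_spacing_nm center-to-center spacing along a row (and
#'   between rows), nm
#' @param v_angle_deg opening angle of the bundle's V, in (0, 180]
#' @param taper_fraction fraction of basal height over which the diameter
#'   shrinks linearly (to 40% of the shaft radius at the base)
#' @param voxel_spacing_nm `(sz, sy, sx)` in nm
#' @param bead_offset_mean_nm,bead_offset_sd_nm radial displacement of bead
#'   centers off the membrane, |N(mean, sd)|
#' @param bead_density_field function `(row, height_fraction, sector,
#'   height_nm) -> beads/um^2`; see [tip_enriched_field()]
#' @param n_decoy_beads beads placed farther than `decoy_min_distance_nm`
#'   from every surface
#' @param decoy_min_distance_nm analytic clearance for decoys; default 125
#'   (= 100 nm discard cutoff + one voxel diagonal, so decoys stay beyond
#'   the cutoff even from the rasterized surface)
#' @param max_voxels sizing guard for the rasterized volume
#' @param rng_seed integer seed; identical spec + seed gives identical output
#' @return object of class `bundle_phantom_spec`
#' @export
bundle_phantom_spec <- function(
    n_cilia_per_row = c(tall = 6L, middle = 6L, short = 6L),
    row_height_mean_nm = c(tall = 2390, middle = 1930, short = 1240),
    row_height_sd_nm = c(tall = 160, middle = 140, short = 70),
    row_diameter_nm = c(tall = 157, middle = 182, short = 129),
    inter_cilium_spacing_nm = 400,
    v_angle_deg = 90,
    taper_fraction = 0.15,
    voxel_spacing_nm = c(15, 10, 10),
    bead_offset_mean_nm = 15,
    bead_offset_sd_nm = 5,
    bead_density_field = tip_enriched_field(),
    n_decoy_beads = 20L,
    decoy_min_distance_nm = 125,
    max_voxels = 5e7,
    rng_seed = 1L) {
  rows <- c("tall", "middle", "short")
  for (nm in c("n_cilia_per_row", "row_height_mean_nm", "row_height_sd_nm",
               "row_diameter_nm")) {
    v <- get(nm)
    if (!all(rows %in% names(v))) stop(nm, " must be named for rows ",
                                       paste(rows, collapse = ", "))
    if (any(!is.finite(v)) || any(v[rows] < 0)) stop(nm, " must be finite and >= 0")
  }
  if (any(row_height_mean_nm[rows] <= 0) || any(row_diameter_nm[rows] <= 0))
    stop("heights and diameters must be > 0")
  if (!(v_angle_deg > 0 && v_angle_deg <= 180))
    stop("v_angle_deg must be in (0, 180]")
  if (inter_cilium_spacing_nm <= 0) stop("inter_cilium_spacing_nm must be > 0")
  if (!(taper_fraction >= 0 && taper_fraction < 1))
    stop("taper_fraction must be in [0, 1)")
  if (any(voxel_spacing_nm <= 0)) stop("voxel_spacing_nm must be > 0")
  if (bead_offset_mean_nm < 0 || bead_offset_sd_nm < 0)
    stop("bead offset parameters must be >= 0")
  if (!is.function(bead_density_field))
    stop("bead_density_field must be a function")
  structure(as.list(environment())[c(
    "n_cilia_per_row", "row_height_mean_nm", "row_height_sd_nm",
    "row_diameter_nm", "inter_cilium_spacing_nm", "v_angle_deg",
    "taper_fraction", "voxel_spacing_nm", "bead_offset_mean_nm",
    "bead_offset_sd_nm", "bead_density_field", "n_decoy_beads",
    "decoy_min_distance_nm", "max_voxels", "rng_seed")],
    class = "bundle_phantom_spec")
}

# analytic radius profile of a capped, basally tapered cylinder at height h
cilium_radius_at <- function(h, height, radius, taper_fraction,
                             taper_tip_ratio = 0.4) {
  r <- rep(NA_real_, length(h))
  taper_h <- taper_fraction * height
  cap_base <- max(height - radius, taper_h)
  in_taper <- h >= 0 & h < taper_h
  in_shaft <- h >= taper_h & h <= cap_base
  in_cap <- h > cap_base & h <= height
  r[in_taper] <- radius * (taper_tip_ratio +
                             (1 - taper_tip_ratio) * h[in_taper] / taper_h)
  r[in_shaft] <- radius
  cap_r <- height - cap_base
  r[in_cap] <- sqrt(pmax(cap_r^2 - (h[in_cap] - cap_base)^2, 0)) *
    (radius / cap_r)
  r[h < 0 | h > height] <- 0
  r
}

# deterministic bundle layout: base centers, per-cilium heights and the true
# local mechanosensitivity normal of each cilium (unit, in the xy-plane)
bundle_layout <- function(spec) {
  rows <- c("short", "middle", "tall")   # increasing y: mechano = +y
  sp <- spec$inter_cilium_spacing_nm
  arm <- (90 - spec$v_angle_deg / 2) * pi / 180  # 0 for a straight row
  out <- list()
  lab <- 0L
  for (ri in seq_along(rows)) {
    rw <- rows[ri]
    n <- spec$n_cilia_per_row[[rw]]
    if (n < 1) next
    y_row <- (ri - 1) * sp
    for (i in seq_len(n)) {
      t <- i - (n + 1) / 2
      lab <- lab + 1L
      # arm tangent (x, y): vertex at t = 0, arms swept toward -y
      tangent_xy <- c(cos(arm), -sign(t) * sin(arm))
      if (t == 0) tangent_xy <- c(1, 0)
      normal_xy <- c(-tangent_xy[2], tangent_xy[1])
      if (normal_xy[2] < 0) normal_xy <- -normal_xy   # toward +y (tall row)
      out[[lab]] <- list(
        label = lab, row = rw,
        center_xy = c(t * sp * cos(arm), y_row - abs(t) * sp * sin(arm)),
        normal_xy = normal_xy)
    }
  }
  out
}

#' Generate a bundle phantom with ground truth
#'
#' Rasterizes the bundle into a label volume, draws beads from the spec's
#' intensity field by an inhomogeneous Poisson draw per (height bin, sector)
#' patch of each cilium's surface, displaces them radially outward, adds
#' decoys, and records everything in ground-truth tables.
#'
#' @param spec a [bundle_phantom_spec()]
#' @return list with `volume` (an [annotated_volume()] holding the label
#'   volume, a bead voxel mask and the bead centroid table), `ground_truth`
#'   (data.frame, one row per bead: cilium_id, row, height_fraction,
#'   azimuth_deg, sector, offset_nm, decoy, centroid coordinates) and
#'   `cilia` (data.frame of true per-cilium geometry)
#' @export
generate_bundle_phantom <- function(spec) {
  stopifnot(inherits(spec, "bundle_phantom_spec"))
  vs <- spec$voxel_spacing_nm
  layout <- bundle_layout(spec)

  truth_cilia <- with_seed(spec$rng_seed, {
    do.call(rbind, lapply(layout, function(L) {
      h <- stats::rnorm(1, spec$row_height_mean_nm[[L$row]],
                        spec$row_height_sd_nm[[L$row]])
      h <- max(h, 4 * spec$row_diameter_nm[[L$row]])
      data.frame(cilium_id = L$label, row = L$row,
                 center_x_nm = L$center_xy[1], center_y_nm = L$center_xy[2],
                 height_nm = h,
                 diameter_nm = spec$row_diameter_nm[[L$row]],
                 normal_x = L$normal_xy[1], normal_y = L$normal_xy[2])
    }))
  })

  margin <- 300
  x_rng <- range(truth_cilia$center_x_nm) + c(-1, 1) * margin
  y_rng <- range(truth_cilia$center_y_nm) + c(-1, 1) * margin
  z_max <- max(truth_cilia$height_nm) + 200
  # shift so all coordinates are >= 0 (cilium bases at z = 0)
  shift <- c(0, -y_rng[1], -x_rng[1])
  truth_cilia$center_x_nm <- truth_cilia$center_x_nm + shift[3]
  truth_cilia$center_y_nm <- truth_cilia$center_y_nm + shift[2]
  dims <- c(floor(z_max / vs[1]) + 1L,
            floor((y_rng[2] - y_rng[1]) / vs[2]) + 1L,
            floor((x_rng[2] - x_rng[1]) / vs[3]) + 1L)
  if (prod(dims) > spec$max_voxels)
    stop("phantom volume of ", paste(dims, collapse = " x "),
         " voxels (z y x) exceeds the budget of ", spec$max_voxels,
         " voxels; shrink the bundle or coarsen voxel_spacing_nm")

  labels <- array(0L, dim = dims)
  for (ci in seq_len(nrow(truth_cilia))) {
    tc <- truth_cilia[ci, ]
    R <- tc$diameter_nm / 2
    jr <- floor((tc$center_y_nm - R - vs[2]) / vs[2]):ceiling((tc$center_y_nm + R + vs[2]) / vs[2])
    ir <- floor((tc$center_x_nm - R - vs[3]) / vs[3]):ceiling((tc$center_x_nm + R + vs[3]) / vs[3])
    jr <- jr[jr >= 0 & jr < dims[2]]
    ir <- ir[ir >= 0 & ir < dims[3]]
    yy <- jr * vs[2] - tc$center_y_nm
    xx <- ir * vs[3] - tc$center_x_nm
    rho2 <- outer(yy^2, xx^2, "+")
    for (k in 0:floor(tc$height_nm / vs[1])) {
      r <- cilium_radius_at(k * vs[1], tc$height_nm, R, spec$taper_fraction)
      if (is.na(r) || r <= 0) next
      hit <- which(rho2 <= r^2, arr.ind = TRUE)
      if (nrow(hit))
        labels[cbind(k + 1L, jr[hit[, 1]] + 1L, ir[hit[, 2]] + 1L)] <- tc$cilium_id
    }
  }

  gt <- with_seed(spec$rng_seed + 1L, {
    recs <- list()
    hf_step <- 0.05
    for (ci in seq_len(nrow(truth_cilia))) {
      tc <- truth_cilia[ci, ]
      R <- tc$diameter_nm / 2
      m_loc <- c(tc$normal_x, tc$normal_y)          # (x, y) local normal
      l_loc <- c(-m_loc[2], m_loc[1])               # +l = axis(+z) x m
      hf_lo <- seq(0, 1 - hf_step, by = hf_step)
      for (lo in hf_lo) for (sec in seq_len(4)) {
        hf_mid <- lo + hf_step / 2
        rate <- spec$bead_density_field(tc$row, hf_mid, SECTOR_LEVELS[sec],
                                        tc$height_nm)
        patch_um2 <- (2 * pi * R * tc$height_nm * hf_step / 4) * 1e-6
        n <- stats::rpois(1, rate * patch_um2)
        if (n == 0) next
        hf <- stats::runif(n, lo, lo + hf_step)
        az_center <- c(0, 90, 180, -90)[sec]
        az <- wrap_deg(az_center + stats::runif(n, -45, 45))
        off <- abs(stats::rnorm(n, spec$bead_offset_mean_nm,
                                spec$bead_offset_sd_nm))
        h <- hf * tc$height_nm
        r_surf <- cilium_radius_at(h, tc$height_nm, R, spec$taper_fraction)
        dir_x <- cos(az * pi / 180) * m_loc[1] + sin(az * pi / 180) * l_loc[1]
        dir_y <- cos(az * pi / 180) * m_loc[2] + sin(az * pi / 180) * l_loc[2]
        recs[[length(recs) + 1L]] <- data.frame(
          cilium_id = tc$cilium_id, row = tc$row, height_fraction = hf,
          azimuth_deg = az, sector = SECTOR_LEVELS[sec], offset_nm = off,
          decoy = FALSE,
          z_nm = h,
          y_nm = tc$center_y_nm + (r_surf + off) * dir_y,
          x_nm = tc$center_x_nm + (r_surf + off) * dir_x)
      }
    }
    beads <- if (length(recs)) do.call(rbind, recs) else
      data.frame(cilium_id = integer(), row = character(),
                 height_fraction = numeric(), azimuth_deg = numeric(),
                 sector = character(), offset_nm = numeric(),
                 decoy = logical(), z_nm = numeric(), y_nm = numeric(),
                 x_nm = numeric())

    if (spec$n_decoy_beads > 0) {
      upper <- (dims - 1) * vs
      placed <- 0L
      dec <- vector("list", spec$n_decoy_beads)
      guard <- 0L
      while (placed < spec$n_decoy_beads) {
        guard <- guard + 1L
        if (guard > 10000L * spec$n_decoy_beads)
          stop("could not place decoy beads beyond ",
               spec$decoy_min_distance_nm, " nm; volume too crowded")
        p <- stats::runif(3) * upper
        # lower bound on surface distance: distance to the axis segment of
        # each cilium minus its shaft radius
        clear <- min(vapply(seq_len(nrow(truth_cilia)), function(ci) {
          tc <- truth_cilia[ci, ]
          dz <- max(0, p[1] - tc$height_nm, -p[1])
          rho <- sqrt((p[2] - tc$center_y_nm)^2 + (p[3] - tc$center_x_nm)^2)
          sqrt(max(rho - tc$diameter_nm / 2, 0)^2 + dz^2)
        }, numeric(1)))
        if (clear > spec$decoy_min_distance_nm) {
          placed <- placed + 1L
          dec[[placed]] <- data.frame(
            cilium_id = NA_integer_, row = NA_character_,
            height_fraction = NA_real_, azimuth_deg = NA_real_,
            sector = NA_character_, offset_nm = NA_real_, decoy = TRUE,
            z_nm = p[1], y_nm = p[2], x_nm = p[3])
        }
      }
      beads <- rbind(beads, do.call(rbind, dec))
    }
    if (nrow(beads)) beads <- cbind(bead_id = seq_len(nrow(beads)), beads)
    else beads <- cbind(data.frame(bead_id = integer()), beads)
    rownames(beads) <- NULL
    beads
  })

  bead_vol <- array(0L, dim = dims)
  if (nrow(gt)) {
    vox <- cbind(pmin(pmax(round(gt$z_nm / vs[1]), 0), dims[1] - 1) + 1L,
                 pmin(pmax(round(gt$y_nm / vs[2]), 0), dims[2] - 1) + 1L,
                 pmin(pmax(round(gt$x_nm / vs[3]), 0), dims[3] - 1) + 1L)
    bead_vol[vox] <- 1L
  }
  centroids <- data.frame(bead_id = gt$bead_id, z_nm = gt$z_nm,
                          y_nm = gt$y_nm, x_nm = gt$x_nm)

  label_table <- data.frame(label = truth_cilia$cilium_id, bundle = "b1",
                            row = truth_cilia$row)
  vol <- annotated_volume(labels, vs,
                          apical_direction = c(1, 0, 0),
                          mechano_direction = c(0, 1, 0),
                          label_table = label_table,
                          beads = bead_vol, bead_centroids = centroids)
  list(volume = vol, ground_truth = gt, cilia = truth_cilia)
}

#' Write a bundle phantom to disk
#'
#' Label and bead volumes as multi-page 16-bit TIFF, bead centroids and
#' ground truth as CSV, metadata as JSON.
#'
#' @param phantom result of [generate_bundle_phantom()]
#' @param dir output directory
#' @return named list of paths, invisibly
#' @export
write_bundle_phantom <- function(phantom, dir) {
  paths <- write_annotated_volume(phantom$volume, dir, basename = "phantom")
  paths$ground_truth <- file.path(dir, "phantom_ground_truth.csv")
  utils::write.csv(phantom$ground_truth, paths$ground_truth, row.names = FALSE)
  paths$cilia <- file.path(dir, "phantom_cilia.csv")
  utils::write.csv(phantom$cilia, paths$cilia, row.names = FALSE)
  invisible(paths)
}
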