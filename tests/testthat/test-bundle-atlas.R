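# bundle_atlas: segment counts, sectors, areas, azimuth correction,
# canonicalization and the density map.

test_that("segment counts reproduce the printed row values", {
  expect_identical(n_segments_for(2390), 12L)
  expect_identical(n_segments_for(1930), 10L)
  expect_identical(n_segments_for(1240), 6L)
  expect_identical(n_segments_for(90), 1L)        # floor at 1
  expect_error(n_segments_for(-1), "positive")
})

test_that("sector convention and exhaustive angle check", {
  expect_equal(sector_of(0), "anterior")
  expect_equal(sector_of(-180), "posterior")
  expect_equal(sector_of(90), "lateral_left")
  expect_equal(sector_of(-90), "lateral_right")
  # boundary membership: [-45, 45) anterior, [45, 135) left, [135, 180) and
  # [-180, -135) posterior, [-135, -45) right
  expect_equal(sector_of(c(-45, 45, 135, -135)),
               c("anterior", "lateral_left", "posterior", "lateral_right"))
  # independent check over random azimuths away from boundaries
  set.seed(2)
  az <- runif(500, -180, 180)
  az <- az[pmin(abs(az %% 90), 90 - abs(az %% 90)) > 1e-6 &
             abs(abs(az) - 45) > 1e-6 & abs(abs(az) - 135) > 1e-6]
  ref <- ifelse(abs(az) < 45, "anterior",
         ifelse(abs(az) > 135, "posterior",
         ifelse(az > 0, "lateral_left", "lateral_right")))
  expect_equal(sector_of(az), ref)
})

test_that("sector areas reproduce the printed per-row values", {
  expect_equal(round(sector_area_um2(157), 3), 0.025)
  expect_lt(abs(sector_area_um2(182) - 0.028), 0.001)
  expect_lt(abs(sector_area_um2(129) - 0.021), 0.001)
  expect_equal(sector_area_um2(0), 0)
})

# --- fixtures for canonical-frame tests: vertical cilia, apical = +z ------

atlas_geom <- function(center_yx, id, length_nm = 1500, radius_nm = 75,
                       row = "tall", seed = 1) {
  cloud <- cylinder_cloud(1200, length_nm = length_nm, radius_nm = radius_nm,
                          center = c(0, center_yx[1], center_yx[2]),
                          axis = c(1, 0, 0), seed = seed)
  make_geometry(cloud, c(1, 0, 0), cilium_id = id, row = row)
}

test_that("azimuth correction: straight row 0, inclined arm 30 degrees, singleton identity", {
  mech <- c(0, 1, 0)
  # straight row along x, already perpendicular to mechano (+y)
  g1 <- atlas_geom(c(0, 0), 1L, seed = 11)
  g2 <- atlas_geom(c(0, 400), 2L, seed = 12)
  g3 <- atlas_geom(c(0, 800), 3L, seed = 13)
  corr <- azimuth_correction(g2, list(g1, g3), mech)
  expect_lt(abs(corr$angle_rad), 0.02)

  # arm inclined 30 degrees to the mechano-normal: bases along
  # (cos30, sin30) in (x, y) => local normal 30 degrees off +y
  a30 <- pi / 6
  h1 <- atlas_geom(c(0, 0), 1L, seed = 21)
  h2 <- atlas_geom(400 * c(sin(a30), cos(a30)), 2L, seed = 22)
  h3 <- atlas_geom(800 * c(sin(a30), cos(a30)), 3L, seed = 23)
  corr30 <- azimuth_correction(h2, list(h1, h3), mech)
  expect_close(abs(corr30$angle_rad) * 180 / pi, 30, 1.5)

  # single-cilium row: identity with a warning
  expect_warning(c0 <- azimuth_correction(g1, list(), mech), "no same-row")
  expect_equal(c0$rotation, diag(3))

  # degenerate: neighbors stacked along the cilium axis
  gz <- atlas_geom(c(0, 0), 9L, seed = 31)
  gz_up <- gz; gz_up$base_centroid_nm <- gz$base_centroid_nm + c(2000, 0, 0)
  expect_error(azimuth_correction(gz, list(gz_up), mech), "parallel to the axis")
})

test_that("canonicalize: height scale, tip beads, and rigid-rotation invariance", {
  mech <- c(0, 1, 0)
  g_tall <- atlas_geom(c(0, 0), 1L, length_nm = 1500, seed = 41)
  g_short <- atlas_geom(c(0, 400), 2L, length_nm = 1200, seed = 42)
  row_max <- max(g_tall$height_nm, g_short$height_nm)
  # bead exactly at the estimated tip
  beads <- data.frame(bead_id = 1L,
                      surface_z_nm = g_short$tip_nm[1],
                      surface_y_nm = g_short$tip_nm[2],
                      surface_x_nm = g_short$tip_nm[3])
  cc_tall <- canonicalize(g_tall, diag(3), row_max, mech)
  cc_short <- canonicalize(g_short, diag(3), row_max, mech, beads = beads)
  expect_equal(cc_tall$height_scale, 1.0)
  expect_lt(cc_short$height_scale, 1.0)
  expect_equal(cc_short$beads$height_fraction, 1.0, tolerance = 1e-9)
  expect_error(canonicalize(g_tall, diag(3), g_tall$height_nm / 2, mech),
               "row_max_height")

  # rotating the whole world (points, beads, apical, mechano) leaves the
  # canonical records unchanged
  set.seed(5)
  Rm <- rotation_about_axis(unit_vec(rnorm(3)), runif(1, 0, 2 * pi))
  rot_pts <- g_short$surface_points %*% t(Rm)
  g_rot <- make_geometry(rot_pts, as.vector(Rm %*% c(1, 0, 0)),
                         cilium_id = 2L)
  b_rot <- as.matrix(beads[, 2:4]) %*% t(Rm)
  beads_rot <- data.frame(bead_id = 1L, surface_z_nm = b_rot[1],
                          surface_y_nm = b_rot[2], surface_x_nm = b_rot[3])
  cc_rot <- canonicalize(g_rot, diag(3), row_max,
                         as.vector(Rm %*% mech), beads = beads_rot)
  expect_equal(cc_rot$beads$height_fraction, cc_short$beads$height_fraction,
               tolerance = 1e-6)
  expect_equal(cc_rot$beads$azimuth_deg, cc_short$beads$azimuth_deg,
               tolerance = 1e-3)
  expect_equal(cc_rot$height_scale, cc_short$height_scale, tolerance = 1e-6)
})

test_that("density map: zero beads, stated arithmetic, bin partition", {
  mech <- c(0, 1, 0)
  geoms <- list(atlas_geom(c(0, 0), 1L, seed = 51),
                atlas_geom(c(0, 400), 2L, seed = 52))
  empty <- structure(data.frame(
    bead_id = integer(), cilium_id = integer(), distance_nm = numeric(),
    nearest_distance_nm = numeric(), surface_z_nm = numeric(),
    surface_y_nm = numeric(), surface_x_nm = numeric(),
    discarded = logical(), reason = character()),
    class = c("projected_beads", "data.frame"))
  canonical <- canonicalize_bundle(geoms, empty, mech)
  dm <- compute_density_map(canonical, row_diameters = c(tall = 157))
  expect_true(all(dm$rows$tall$counts == 0))
  expect_true(all(dm$rows$tall$density == 0))

  # stated formula: 3 beads in one bin, 200 cilia, area 0.025 -> 0.6
  expect_equal(3 / (0.025 * 200), 0.6)

  # partition: random beads on both cilia all land in exactly one bin
  set.seed(77)
  n_b <- 120
  pick <- sample(1:2, n_b, replace = TRUE)
  surf <- t(vapply(seq_len(n_b), function(i) {
    p <- geoms[[pick[i]]]$surface_points
    p[sample(nrow(p), 1), ]
  }, numeric(3)))
  proj <- structure(data.frame(
    bead_id = seq_len(n_b), cilium_id = pick, distance_nm = 0,
    nearest_distance_nm = 0, surface_z_nm = surf[, 1],
    surface_y_nm = surf[, 2], surface_x_nm = surf[, 3],
    discarded = FALSE, reason = NA_character_),
    class = c("projected_beads", "data.frame"))
  canonical2 <- canonicalize_bundle(geoms, proj, mech)
  dm2 <- compute_density_map(canonical2, row_diameters = c(tall = 150))
  expect_equal(sum(dm2$rows$tall$counts), n_b)
  expect_equal(dm2$rows$tall$density,
               dm2$rows$tall$counts / (dm2$rows$tall$sector_area_um2 * 2))
  # beads referencing an unknown cilium raise a consistency error
  bad <- proj; bad$cilium_id[1] <- 99L
  expect_error(canonicalize_bundle(geoms, bad, mech), "unknown cilium")
})

test_that("uniform-intensity beads give near-uniform per-bin densities", {
  # uniform bead placement on a cylinder -> equal expected density per bin;
  # each realized bin count stays within 3 Poisson SDs of the mean
  mech <- c(0, 1, 0)
  set.seed(31)
  g <- atlas_geom(c(0, 0), 1L, length_nm = 1600, seed = 61)
  n_b <- 1200
  th <- runif(n_b, -pi, pi); hgt <- runif(n_b, 0, 1600)
  surf <- cbind(hgt, 75 * cos(th), 75 * sin(th))
  proj <- structure(data.frame(
    bead_id = seq_len(n_b), cilium_id = 1L, distance_nm = 0,
    nearest_distance_nm = 0, surface_z_nm = surf[, 1],
    surface_y_nm = surf[, 2], surface_x_nm = surf[, 3],
    discarded = FALSE, reason = NA_character_),
    class = c("projected_beads", "data.frame"))
  expect_warning(canonical <- canonicalize_bundle(list(g), proj, mech),
                 "no same-row")
  dm <- compute_density_map(canonical, row_diameters = c(tall = 150))
  counts <- as.vector(dm$rows$tall$counts)
  mu <- n_b / length(counts)
  expect_true(all(abs(counts - mu) <= 3 * sqrt(mu)))
})

test_that("representative surface recovers the mean radius of overlaid cylinders", {
  mech <- c(0, 1, 0)
  geoms <- lapply(1:4, function(i)
    atlas_geom(c(0, 400 * (i - 1)), i, length_nm = 1500, radius_nm = 80,
               seed = 70 + i))
  empty <- structure(data.frame(
    bead_id = integer(), cilium_id = integer(), distance_nm = numeric(),
    nearest_distance_nm = numeric(), surface_z_nm = numeric(),
    surface_y_nm = numeric(), surface_x_nm = numeric(),
    discarded = logical(), reason = character()),
    class = c("projected_beads", "data.frame"))
  canonical <- canonicalize_bundle(geoms, empty, mech)
  cloud <- representative_surface(canonical, "tall", target_points = 1500,
                                  seed = 2)
  expect_lte(nrow(cloud), 1500)
  # fitted mean radius over the shaft mid-band
  mid <- cloud[, "h"] > 400 & cloud[, "h"] < 1100
  r <- sqrt(cloud[mid, "m"]^2 + cloud[mid, "l"]^2)
  expect_close(mean(r), 80, 4)
  # single cilium returns its own canonical cloud
  one <- representative_surface(canonical[1], "tall", target_points = 1e6)
  expect_equal(nrow(one), nrow(canonical[[1]]$surface_hml))
  expect_error(representative_surface(canonical, "kinocilium"), "no canonical")
})
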