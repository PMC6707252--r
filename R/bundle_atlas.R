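# Canonical bundle frame and the segment-by-sector density map.
#
# Each cilium (with its assigned beads) is moved into a canonical frame:
# taper at the origin, axis along +h, and an azimuth rotation about the axis
# that opens the bundle's V so every cilium faces the same mechanosensitivity
# plane. Heights are expressed as fractions of each cilium's own height, so
# overlaid tips coincide at fraction 1. Beads are then binned into
# `n_segments` equal height-fraction segments (the segment count comes from
# the row's mean height at 200 nm per segment) times four radial sectors,
# and density is count / (sector area x number of overlaid cilia).

SECTOR_LEVELS <- c("anterior", "lateral_left", "posterior", "lateral_right")

#' Number of longitudinal segments for a row
#'
#' Nearest integer to `row_mean_height_nm / segment_height_nm`, minimum 1.
#' At the canonical 200-nm segment height, rows of mean height 2390, 1930
#' and 1240 nm give 12, 10 and 6 segments.
#'
#' @param row_mean_height_nm mean cilium height of the row, nm
#' @param segment_height_nm nominal segment height, nm (default 200)
#' @return integer segment count
#' @export
n_segments_for <- function(row_mean_height_nm, segment_height_nm = 200) {
  if (any(row_mean_height_nm <= 0) || any(segment_height_nm <= 0))
    stop("heights must be positive")
  pmax(1L, as.integer(floor(row_mean_height_nm / segment_height_nm + 0.5)))
}

#' Radial sector of an azimuth angle
#'
#' Azimuth 0 faces the positive mechanosensitivity direction (toward the
#' tallest row). Quadrants: anterior [-45, 45), lateral_left [45, 135),
#' posterior [135, 180) and [-180, -135), lateral_right [-135, -45).
#'
#' @param azimuth_deg angle(s) in [-180, 180)
#' @return character vector of sector names
#' @export
sector_of <- function(azimuth_deg) {
  a <- wrap_deg(azimuth_deg)
  out <- character(length(a))
  out[a >= -45 & a < 45] <- "anterior"
  out[a >= 45 & a < 135] <- "lateral_left"
  out[a >= 135 | a < -135] <- "posterior"
  out[a >= -135 & a < -45] <- "lateral_right"
  out
}

#' Area of one radial sector of a segment, in um^2
#'
#' One of four equal radial sectors of a cylindrical shell of the row's mean
#' diameter: (pi * d * segment_height) / 4.
#'
#' @param diameter_nm mean stereocilium diameter of the row, nm
#' @param segment_height_nm segment height, nm (default 200)
#' @return area in um^2
#' @export
sector_area_um2 <- function(diameter_nm, segment_height_nm = 200) {
  if (any(diameter_nm < 0) || any(segment_height_nm <= 0))
    stop("diameter must be >= 0 and segment height > 0")
  (pi * diameter_nm * segment_height_nm / 4) * 1e-6
}

#' Azimuth correction angle for one cilium
#'
#' The local row tangent is the unit vector between the base centroids of
#' the cilium's two nearest same-row neighbors (at a row end, the vector to
#' its single neighbor). The local mechanosensitivity normal is the in-plane
#' (perpendicular to the cilium axis) normal of that tangent, signed toward
#' the global mechano direction. The returned rotation about the cilium axis
#' maps the local normal onto the global mechano direction, opening the
#' bundle's V.
#'
#' @param cilium a `cilium_geometry`
#' @param row_neighbors list of same-row `cilium_geometry` (excluding
#'   `cilium` itself); empty list gives the identity with a warning
#' @param mechano_direction global unit vector, shortest -> tallest row
#' @return list with `angle_rad` and the 3x3 `rotation` matrix (acts on
#'   (z, y, x) column vectors about the cilium axis)
#' @export
azimuth_correction <- function(cilium, row_neighbors, mechano_direction) {
  a <- unit_vec(cilium$axis)
  if (!length(row_neighbors)) {
    warning("cilium ", cilium$cilium_id,
            " has no same-row neighbors; azimuth correction is the identity",
            call. = FALSE)
    return(list(angle_rad = 0, rotation = diag(3)))
  }
  bases <- t(vapply(row_neighbors, function(g) g$base_centroid_nm, numeric(3)))
  dists <- sqrt(rowSums(sweep(bases, 2, cilium$base_centroid_nm)^2))
  nn <- order(dists)[seq_len(min(2L, nrow(bases)))]
  tangent <- if (length(nn) == 2L) bases[nn[2], ] - bases[nn[1], ]
             else bases[nn[1], ] - cilium$base_centroid_nm
  # project tangent and mechano direction into the plane perpendicular to the axis
  t_in <- tangent - sum(tangent * a) * a
  # reject tangents within ~1 degree of the axis: the in-plane direction is
  # then set by segmentation noise, not by row geometry
  if (sqrt(sum(t_in^2)) < 0.02 * sqrt(sum(tangent^2)))
    stop("degenerate neighbor geometry: row tangent is parallel to the axis")
  t_in <- unit_vec(t_in)
  normal <- cross3(a, t_in)
  if (sum(normal * mechano_direction) < 0) normal <- -normal
  m_in <- mechano_direction - sum(mechano_direction * a) * a
  if (sqrt(sum(m_in^2)) < 1e-9)
    stop("mechano direction is parallel to the cilium axis")
  m_in <- unit_vec(m_in)
  angle <- signed_angle_about(normal, m_in, a)
  list(angle_rad = angle, rotation = rotation_about_axis(a, angle))
}

#' Move a cilium and its beads into the canonical frame
#'
#' Applies the azimuth rotation about the cilium axis, translates the taper
#' to the origin, and rotates the axis onto +h. Canonical coordinates are
#' (h, m, l): h along the cilium axis, m the mechanosensitivity direction, l
#' completing a right-handed frame. Height fractions are per-cilium
#' (axial coordinate / this cilium's height, clamped to [0, 1]) so tips
#' coincide at fraction 1 across a row; azimuth is measured from +m,
#' positive toward +l (counterclockwise viewed from the tip).
#'
#' @param cilium a `cilium_geometry`
#' @param rotation azimuth rotation from [azimuth_correction()] (3x3 matrix)
#' @param row_max_height tallest cilium height of the row, nm (>= this
#'   cilium's height)
#' @param mechano_direction global mechanosensitivity unit vector
#' @param beads optional `projected_beads` rows assigned to this cilium;
#'   their surface points are canonicalized alongside the cloud
#' @return object of class `canonical_cilium` with `surface_hml` (n x 3,
#'   columns h/m/l in nm), `height_scale`, and `beads` (data.frame with
#'   `bead_id, height_fraction, azimuth_deg`)
#' @export
canonicalize <- function(cilium, rotation, row_max_height, mechano_direction,
                         beads = NULL) {
  if (row_max_height < cilium$height_nm - 1e-6)
    stop("row_max_height is smaller than the cilium height")
  a <- unit_vec(cilium$axis)
  m_in <- mechano_direction - sum(mechano_direction * a) * a
  m_in <- unit_vec(m_in)
  # after the azimuth rotation the local normal coincides with m_in
  l_vec <- cross3(a, m_in)          # h x m = l: (h, m, l) right-handed
  basis <- rbind(h = a, m = m_in, l = l_vec)

  to_canonical <- function(p) {
    rel <- sweep(as.matrix(p), 2, cilium$taper_nm)
    rot <- t(rotation %*% t(rel))   # azimuth rotation about the axis (at taper)
    t(basis %*% t(rot))
  }
  surf <- to_canonical(cilium$surface_points)
  colnames(surf) <- c("h", "m", "l")

  bead_df <- NULL
  if (!is.null(beads) && nrow(beads)) {
    sp <- to_canonical(beads[, c("surface_z_nm", "surface_y_nm",
                                 "surface_x_nm")])
    hf <- pmin(pmax(sp[, 1] / cilium$height_nm, 0), 1)
    az <- wrap_deg(atan2(sp[, 3], sp[, 2]) * 180 / pi)
    bead_df <- data.frame(bead_id = beads$bead_id, height_fraction = hf,
                          azimuth_deg = az, sector = sector_of(az))
  }
  structure(list(cilium_id = cilium$cilium_id, row = cilium$row,
                 surface_hml = surf,
                 height_scale = cilium$height_nm / row_max_height,
                 height_nm = cilium$height_nm, beads = bead_df),
            class = "canonical_cilium")
}

#' Canonicalize every cilium of a bundle
#'
#' Groups cilia by row, computes each cilium's azimuth correction from its
#' same-row neighbors, and canonicalizes cilia together with their assigned
#' beads.
#'
#' @param geoms named list of `cilium_geometry` (from [bundle_geometry()])
#' @param projected `projected_beads` from [project_beads()]
#' @param mechano_direction global mechanosensitivity unit vector
#' @return named list of `canonical_cilium`
#' @export
canonicalize_bundle <- function(geoms, projected, mechano_direction) {
  ids <- vapply(geoms, function(g) g$cilium_id, numeric(1))
  assigned <- projected$cilium_id[!projected$discarded &
                                    !is.na(projected$cilium_id)]
  unknown <- setdiff(assigned, ids)
  if (length(unknown))
    stop("projected beads reference unknown cilium id(s): ",
         paste(unknown, collapse = ", "))
  rows <- vapply(geoms, function(g) g$row, character(1))
  lapply(stats::setNames(seq_along(geoms), names(geoms)), function(i) {
    g <- geoms[[i]]
    mates <- geoms[rows == g$row]
    mates <- mates[vapply(mates, function(x) x$cilium_id != g$cilium_id,
                          logical(1))]
    corr <- azimuth_correction(g, mates, mechano_direction)
    row_max <- max(vapply(geoms[rows == g$row], function(x) x$height_nm,
                          numeric(1)))
    bd <- projected[!projected$discarded &
                      !is.na(projected$cilium_id) &
                      projected$cilium_id == g$cilium_id, , drop = FALSE]
    canonicalize(g, corr$rotation, row_max, mechano_direction, beads = bd)
  })
}

#' Cumulative segment-by-sector bead density map
#'
#' Accumulates canonical bead records into (row, segment, sector) bins.
#' Segment index is `floor(height_fraction * n_segments)` clamped to the top
#' segment; density is count / (sector_area_um2 * n_cilia of the row), in
#' beads per um^2 per cilium.
#'
#' @param canonical list of `canonical_cilium` (see [canonicalize_bundle()])
#' @param row_diameters named numeric, mean diameter (nm) per row (e.g. row
#'   means of [geometry_table()] output)
#' @param segment_height_nm segment height for [n_segments_for()] and
#'   [sector_area_um2()] (default 200)
#' @param include_kinocilium kinocilia are canonicalized but excluded from
#'   the map unless TRUE
#' @return object of class `density_map`
#' @export
compute_density_map <- function(canonical, row_diameters = NULL,
                                segment_height_nm = 200,
                                include_kinocilium = FALSE) {
  rows <- vapply(canonical, function(c) c$row, character(1))
  use_rows <- intersect(c("tall", "middle", "short",
                          if (include_kinocilium) "kinocilium"),
                        unique(rows))
  out_rows <- list()
  for (rw in use_rows) {
    members <- canonical[rows == rw]
    heights <- vapply(members, function(c) c$height_nm, numeric(1))
    n_seg <- n_segments_for(mean(heights), segment_height_nm)
    dia <- if (!is.null(row_diameters) && rw %in% names(row_diameters))
      row_diameters[[rw]] else NA_real_
    if (is.na(dia))
      stop("row_diameters must supply a mean diameter for row '", rw, "'")
    area <- sector_area_um2(dia, segment_height_nm)
    counts <- matrix(0L, n_seg, 4, dimnames = list(NULL, SECTOR_LEVELS))
    for (cc in members) {
      if (is.null(cc$beads) || !nrow(cc$beads)) next
      seg <- pmin(floor(cc$beads$height_fraction * n_seg), n_seg - 1)
      sec <- match(cc$beads$sector, SECTOR_LEVELS)
      for (b in seq_along(seg))
        counts[seg[b] + 1L, sec[b]] <- counts[seg[b] + 1L, sec[b]] + 1L
    }
    n_cilia <- length(members)
    out_rows[[rw]] <- list(n_segments = n_seg, counts = counts,
                           density = counts / (area * n_cilia),
                           sector_area_um2 = area, n_cilia = n_cilia)
  }
  structure(list(rows = out_rows, segment_height_nm = segment_height_nm),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  for (rw in names(x$rows)) {
    r <- x$rows[[rw]]
    cat(sprintf("%s row: %d segments x 4 sectors, %d cilia, %d beads, sector area %.3f um^2\n",
                rw, r$n_segments, r$n_cilia, sum(r$counts), r$sector_area_um2))
  }
  invisible(x)
}

#' Representative overlaid surface for one row
#'
#' Pools the canonical surface points of all cilia of a row and decimates
#' them to a target count with a seeded uniform subsample. Intended for
#' visualization of the average ciliary shape; no triangulation is attempted
#' (point-cloud output only).
#'
#' @param canonical list of `canonical_cilium`
#' @param row row name to overlay
#' @param target_points decimation target (default 2000)
#' @param seed RNG seed for the subsample
#' @return n x 3 matrix of canonical (h, m, l) coordinates in nm
#' @export
representative_surface <- function(canonical, row, target_points = 2000L,
                                   seed = 1L) {
  members <- canonical[vapply(canonical, function(c) c$row == row, logical(1))]
  if (!length(members)) stop("no canonical cilia in row '", row, "'")
  cloud <- do.call(rbind, lapply(members, function(c) c$surface_hml))
  if (nrow(cloud) > target_points) {
    keep <- with_seed(seed, sample.int(nrow(cloud), target_points))
    cloud <- cloud[sort(keep), , drop = FALSE]
  }
  cloud
}
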