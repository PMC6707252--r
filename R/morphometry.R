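# Per-cilium morphometry: surface point clouds, principal axis, tip/taper,
# height and diameter.
#
# Surface extraction mirrors the published workflow: the segmentation is
# downsampled in-plane (the milling axis is already coarse), border voxels of
# each label are taken as the membrane surface, and a seeded 10% subsample of
# those border voxels is carried forward. Acquisition-resolution volumes
# (~2x2x15 nm voxels) with `resize_factor = 4` end up near-isotropic at
# ~10x10x15 nm; phantoms generated directly at that scale use
# `resize_factor = 1`.

#' Downsample a label volume in-plane by majority vote
#'
#' Pools `factor x factor` blocks in (y, x), leaving z untouched. Each pooled
#' voxel takes the most frequent label in its block (ties broken toward the
#' smaller label id; background competes like any label).
#'
#' @param volume integer array `[z, y, x]`
#' @param factor integer >= 1
#' @return list with `volume` (pooled array) and `spacing_scale` `(1, factor,
#'   factor)`
#' @export
downsample_labels <- function(volume, factor = 4L) {
  factor <- as.integer(factor)
  stopifnot(length(dim(volume)) == 3, factor >= 1)
  if (factor == 1L)
    return(list(volume = volume, spacing_scale = c(1, 1, 1)))
  d <- dim(volume)
  ny <- d[2] %/% factor
  nx <- d[3] %/% factor
  if (ny < 1 || nx < 1)
    stop("volume too small to downsample by factor ", factor)
  vtrim <- volume[, seq_len(ny * factor), seq_len(nx * factor), drop = FALSE]
  # reshape to [z, (sub_y, block_y), (sub_x, block_x)] and tabulate per block
  labs <- sort(unique(as.vector(vtrim)))
  # votes[z, by, bx, label]
  best <- array(labs[1], dim = c(d[1], ny, nx))
  best_count <- array(-1L, dim = c(d[1], ny, nx))
  for (lab in rev(labs)) {  # reverse so ties end with the smallest label
    m <- array(as.integer(vtrim == lab), dim = dim(vtrim))
    cnt <- array(0L, dim = c(d[1], ny, nx))
    for (sy in seq_len(factor)) for (sx in seq_len(factor)) {
      cnt <- cnt + m[, seq(sy, ny * factor, by = factor),
                     seq(sx, nx * factor, by = factor), drop = FALSE]
    }
    upd <- cnt >= best_count  # ">=" + reversed label order => ties -> smaller id
    best[upd] <- lab
    best_count[upd] <- cnt[upd]
  }
  list(volume = best, spacing_scale = c(1, factor, factor))
}

#' Border voxels of one label (six-connected background test)
#'
#' A labeled voxel is a border voxel if at least one of its six face
#' neighbors is background (0) or outside the volume.
#'
#' @param volume integer array `[z, y, x]`
#' @param label label id
#' @return logical array, TRUE at border voxels of `label`
#' @keywords internal
border_mask <- function(volume, label) {
  m <- volume == label
  if (!any(m)) stop("label ", label, " not found in volume")
  d <- dim(volume)
  fg <- volume != 0
  shift_bg <- function(axis, dir) {
    # TRUE where the face neighbor along `axis` in direction `dir` is background
    out <- array(TRUE, dim = d)  # boundary faces see background
    if (axis == 1) {
      if (dir > 0) out[seq_len(d[1] - 1), , ] <- !fg[2:d[1], , , drop = FALSE]
      else out[2:d[1], , ] <- !fg[seq_len(d[1] - 1), , , drop = FALSE]
    } else if (axis == 2) {
      if (dir > 0) out[, seq_len(d[2] - 1), ] <- !fg[, 2:d[2], , drop = FALSE]
      else out[, 2:d[2], ] <- !fg[, seq_len(d[2] - 1), , drop = FALSE]
    } else {
      if (dir > 0) out[, , seq_len(d[3] - 1)] <- !fg[, , 2:d[3], drop = FALSE]
      else out[, , 2:d[3]] <- !fg[, , seq_len(d[3] - 1), drop = FALSE]
    }
    out
  }
  bg_neighbor <- shift_bg(1, 1) | shift_bg(1, -1) |
    shift_bg(2, 1) | shift_bg(2, -1) |
    shift_bg(3, 1) | shift_bg(3, -1)
  m & bg_neighbor
}

#' Extract a subsampled surface point cloud for one cilium
#'
#' Downsamples the label volume in-plane by `resize_factor` (majority-vote
#' pooling), finds the label's border voxels on the pooled grid, and returns
#' a seeded uniform `keep_fraction` subset as physical nm coordinates.
#'
#' @param vol an [annotated_volume()]
#' @param cilium_id label id present in `vol`
#' @param resize_factor in-plane pooling factor (default 4; use 1 for
#'   volumes already at analysis scale)
#' @param keep_fraction fraction of border voxels kept, in (0, 1]
#' @param seed RNG seed for the subsample
#' @return n x 3 matrix of nm coordinates (columns z, y, x)
#' @export
extract_surface_points <- function(vol, cilium_id, resize_factor = 4L,
                                   keep_fraction = 0.10, seed = 1L) {
  stopifnot(inherits(vol, "annotated_volume"))
  if (!(keep_fraction > 0 && keep_fraction <= 1))
    stop("keep_fraction must be in (0, 1]")
  if (!cilium_id %in% vol$label_table$label)
    stop("cilium_id ", cilium_id, " not present in label_table")
  ds <- downsample_labels(vol$cilium_labels, resize_factor)
  if (!any(ds$volume == cilium_id))
    stop("label ", cilium_id, " not found after downsampling by ", resize_factor)
  spacing <- vol$spacing_nm * ds$spacing_scale
  bm <- border_mask(ds$volume, cilium_id)
  idx <- which(bm)
  if (!length(idx)) stop("internal: label ", cilium_id, " has no border voxels")
  pts <- idx_to_nm(idx, dim(ds$volume), spacing)
  # pooled voxel centers sit at the mean of their source-voxel centers
  offset <- (ds$spacing_scale - 1) / 2 * vol$spacing_nm
  pts <- sweep(pts, 2, offset, "+")
  if (keep_fraction < 1) {
    n_keep <- max(1L, round(keep_fraction * nrow(pts)))
    keep <- with_seed(seed, sample.int(nrow(pts), n_keep))
    pts <- pts[sort(keep), , drop = FALSE]
  }
  pts
}

#' Estimate a cilium's principal axis and its two ends
#'
#' The axis is the first principal component of the surface cloud, sign-fixed
#' so it points apically (taper -> tip). Tip and taper are means over a thin
#' end band: all points whose axial projection lies within `end_band_frac`
#' of the axial extent of the respective extreme. Averaging a band is robust
#' to single outlying voxels, while keeping the band thin (1% of the extent
#' by default, about one or two milling steps on real volumes) keeps the end
#' estimates unbiased on capped cylinders, where a fixed count quantile
#' would reach far down the shaft.
#'
#' @param points n x 3 matrix of nm coordinates (z, y, x), n >= 20
#' @param apical_direction unit vector toward the bundle tips
#' @param end_band_frac thickness of the end band as a fraction of the
#'   axial extent (default 0.01)
#' @return list with `axis` (unit vector), `tip_nm`, `taper_nm`
#' @export
estimate_axis_and_ends <- function(points, apical_direction,
                                   end_band_frac = 0.01) {
  points <- as.matrix(points)
  if (nrow(points) < 20) stop("need at least 20 surface points")
  pc <- stats::prcomp(points, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (ev[1] > 0 && (ev[1] - ev[2]) / ev[1] < 0.05)
    stop("degenerate point cloud: first two principal values within 5%; ",
         "axis is ambiguous")
  axis <- pc$rotation[, 1]
  if (sum(axis * apical_direction) < 0) axis <- -axis
  proj <- as.vector(points %*% axis)
  band <- end_band_frac * diff(range(proj))
  taper <- colMeans(points[proj <= min(proj) + band, , drop = FALSE])
  tip <- colMeans(points[proj >= max(proj) - band, , drop = FALSE])
  list(axis = as.numeric(axis), tip_nm = as.numeric(tip),
       taper_nm = as.numeric(taper))
}

#' Height and diameter of a cilium from its surface cloud
#'
#' Height is the axial extent tip - taper. Diameter is twice a robust
#' central radius of the axial mid-band (normalized axial position
#' 0.25-0.75, avoiding both the basal taper and the tip cap): the
#' interquartile mean of the radial distances. On symmetric radius
#' distributions this coincides with the median, but it does not jump
#' between discrete voxel shells when the surface cloud is subsampled.
#'
#' @param points n x 3 surface cloud (nm)
#' @param axis unit axis vector (taper -> tip)
#' @param tip_nm,taper_nm end points from [estimate_axis_and_ends()]
#' @return list with `height_nm` and `diameter_nm`
#' @export
measure_cilium <- function(points, axis, tip_nm, taper_nm) {
  points <- as.matrix(points)
  height <- sum((tip_nm - taper_nm) * axis)
  if (height <= 0) return(list(height_nm = max(height, 0), diameter_nm = 0))
  t_axial <- as.vector(sweep(points, 2, taper_nm) %*% axis) / height
  mid <- t_axial >= 0.25 & t_axial <= 0.75
  if (!any(mid)) stop("no surface points in the axial mid-band [0.25, 0.75]")
  # radial distances about the axis line through the mid-band centroid: the
  # centroid is a far steadier center estimate than the (few-point) taper cap
  rel <- sweep(points[mid, , drop = FALSE], 2,
               colMeans(points[mid, , drop = FALSE]))
  ax_comp <- rel %*% axis
  radial <- sqrt(pmax(rowSums(rel^2) - as.vector(ax_comp)^2, 0))
  qs <- stats::quantile(radial, c(0.25, 0.75), names = FALSE)
  central <- radial[radial >= qs[1] & radial <= qs[2]]
  list(height_nm = height, diameter_nm = 2 * mean(central))
}

#' Full geometry for one cilium
#'
#' Convenience wrapper running [extract_surface_points()],
#' [estimate_axis_and_ends()] and [measure_cilium()], and recording the base
#' centroid (mean of the basal 10% of points) used by the azimuth
#' correction.
#'
#' @inheritParams extract_surface_points
#' @return object of class `cilium_geometry`: cilium_id, row, surface_points,
#'   axis, tip_nm, taper_nm, height_nm, diameter_nm, base_centroid_nm
#' @export
cilium_geometry <- function(vol, cilium_id, resize_factor = 4L,
                            keep_fraction = 0.10, seed = 1L) {
  pts <- extract_surface_points(vol, cilium_id, resize_factor, keep_fraction,
                                seed)
  ends <- estimate_axis_and_ends(pts, vol$apical_direction)
  meas <- measure_cilium(pts, ends$axis, ends$tip_nm, ends$taper_nm)
  proj <- as.vector(sweep(pts, 2, ends$taper_nm) %*% ends$axis)
  basal <- pts[proj <= stats::quantile(proj, 0.10), , drop = FALSE]
  row <- vol$label_table$row[match(cilium_id, vol$label_table$label)]
  structure(list(cilium_id = cilium_id, row = row, surface_points = pts,
                 axis = ends$axis, tip_nm = ends$tip_nm,
                 taper_nm = ends$taper_nm, height_nm = meas$height_nm,
                 diameter_nm = meas$diameter_nm,
                 base_centroid_nm = colMeans(basal)),
            class = "cilium_geometry")
}

#' Geometry for every cilium in a volume
#'
#' @inheritParams extract_surface_points
#' @param ids label ids to process (default: all labels in the table)
#' @return named list of `cilium_geometry`, names = label ids
#' @export
bundle_geometry <- function(vol, ids = NULL, resize_factor = 4L,
                            keep_fraction = 0.10, seed = 1L) {
  if (is.null(ids)) ids <- vol$label_table$label
  geoms <- lapply(seq_along(ids), function(i)
    cilium_geometry(vol, ids[i], resize_factor, keep_fraction,
                    seed = seed + i - 1L))
  names(geoms) <- ids
  geoms
}

#' Summarize bundle geometry as a data.frame
#' @param geoms list of `cilium_geometry`
#' @return data.frame, one row per cilium
#' @export
geometry_table <- function(geoms) {
  do.call(rbind, lapply(geoms, function(g)
    data.frame(cilium_id = g$cilium_id, row = g$row,
               height_nm = g$height_nm, diameter_nm = g$diameter_nm,
               axis_z = g$axis[1], axis_y = g$axis[2], axis_x = g$axis[3],
               tip_z_nm = g$tip_nm[1], tip_y_nm = g$tip_nm[2],
               tip_x_nm = g$tip_nm[3], taper_z_nm = g$taper_nm[1],
               taper_y_nm = g$taper_nm[2], taper_x_nm = g$taper_nm[3],
               n_surface_points = nrow(g$surface_points))))
}
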