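# End-to-end driver: from an annotated volume to the density map.

#' Run the full bead-mapping pipeline on an annotated volume
#'
#' Extracts per-cilium geometry, reduces beads to centroids (if supplied as
#' a volume), projects centroids onto the nearest cilium surface by kNN
#' vote, canonicalizes cilia and beads, and accumulates the
#' segment-by-sector density map.
#'
#' @param vol an [annotated_volume()]
#' @param resize_factor in-plane downsampling for surface extraction
#'   (default 4; use 1 for volumes already at ~10 nm in-plane)
#' @param keep_fraction border-voxel subsample fraction (default 0.10)
#' @param k kNN vote size (default 10)
#' @param cutoff_nm bead discard distance (default 100)
#' @param segment_height_nm segment height for the map (default 200)
#' @param row_diameters named mean diameter per row, nm; default: row means
#'   of the measured diameters
#' @param seed RNG seed for the surface subsample
#' @return list with `geometries`, `projected`, `canonical`, `density_map`
#' @export
map_bundle <- function(vol, resize_factor = 4L, keep_fraction = 0.10,
                       k = 10L, cutoff_nm = 100, segment_height_nm = 200,
                       row_diameters = NULL, seed = 1L) {
  stopifnot(inherits(vol, "annotated_volume"))
  geoms <- bundle_geometry(vol, resize_factor = resize_factor,
                           keep_fraction = keep_fraction, seed = seed)
  centroids <- vol$bead_centroids
  if (is.null(centroids)) {
    if (is.null(vol$beads)) stop("volume carries no bead observations")
    centroids <- compute_bead_centroids(vol$beads, vol$spacing_nm)
  }
  projected <- project_beads(centroids, geoms, k = k, cutoff_nm = cutoff_nm)
  canonical <- canonicalize_bundle(geoms, projected, vol$mechano_direction)
  if (is.null(row_diameters)) {
    gt <- geometry_table(geoms)
    gt <- gt[gt$row %in% c("tall", "middle", "short"), ]
    row_diameters <- tapply(gt$diameter_nm, gt$row, mean)
  }
  density <- compute_density_map(canonical, row_diameters = row_diameters,
                                 segment_height_nm = segment_height_nm)
  list(geometries = geoms, projected = projected, canonical = canonical,
       density_map = density)
}

#' Summarize projected beads as a flat table
#'
#' Joins the projection result with the canonical per-bead records
#' (height fraction, azimuth, segment, sector).
#'
#' @param pipeline result of [map_bundle()]
#' @return data.frame, one row per input bead
#' @export
projected_bead_table <- function(pipeline) {
  proj <- as.data.frame(pipeline$projected)
  canon <- do.call(rbind, lapply(pipeline$canonical, function(cc) {
    if (is.null(cc$beads) || !nrow(cc$beads)) return(NULL)
    n_seg <- NULL
    data.frame(bead_id = cc$beads$bead_id,
               height_fraction = cc$beads$height_fraction,
               azimuth_deg = cc$beads$azimuth_deg,
               sector = cc$beads$sector)
  }))
  if (is.null(canon))
    canon <- data.frame(bead_id = integer(), height_fraction = numeric(),
                        azimuth_deg = numeric(), sector = character())
  merge(proj, canon, by = "bead_id", all.x = TRUE, sort = TRUE)
}
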