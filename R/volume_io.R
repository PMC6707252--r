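# Reading, validation and writing of the pipeline's file formats.
#
# Conventions fixed here and relied on everywhere downstream:
#   * arrays are indexed [z, y, x]; vectors use the same (z, y, x) order;
#   * voxel indices are 0-based with a voxel-center convention, so voxel
#     (k, j, i) sits at physical (k*sz, j*sy, i*sx) nanometres;
#   * all coordinates leaving this module are physical nm -- voxel indices
#     never leak into the analysis modules (anisotropic voxels make index
#     arithmetic too error-prone to pass around).

ROW_LEVELS <- c("tall", "middle", "short", "kinocilium")

#' Construct and validate an annotated volume
#'
#' Bundles a cilium label volume, bead observations (label volume on the same
#' grid and/or a centroid table in nm), voxel spacing and orientation
#' metadata into one validated object, the raw input of the mapping pipeline.
#'
#' @param cilium_labels integer array `[z, y, x]`, 0 = background
#' @param spacing_nm numeric length-3 `(sz, sy, sx)`, strictly positive
#' @param apical_direction length-3 vector in the (z, y, x) physical frame
#'   pointing from the cell body toward the bundle tips; normalized (with a
#'   warning if not already unit length)
#' @param mechano_direction length-3 vector, positive sense from the shortest
#'   toward the tallest stereocilia row; normalized like `apical_direction`
#' @param label_table data.frame with columns `label` (integer), `bundle`,
#'   `row` (one of tall/middle/short/kinocilium); every nonzero label in the
#'   volume must appear here
#' @param beads optional bead label/mask volume congruent with
#'   `cilium_labels`
#' @param bead_centroids optional data.frame `bead_id, z_nm, y_nm, x_nm`
#' @return object of class `annotated_volume`
#' @export
annotated_volume <- function(cilium_labels, spacing_nm, apical_direction,
                             mechano_direction, label_table,
                             beads = NULL, bead_centroids = NULL) {
  if (length(dim(cilium_labels)) != 3)
    stop("cilium_labels must be a 3D array [z, y, x]")
  spacing_nm <- as.numeric(spacing_nm)
  if (length(spacing_nm) != 3 || any(!is.finite(spacing_nm)) || any(spacing_nm <= 0))
    stop("spacing_nm must be three strictly positive finite numbers (sz, sy, sx)")

  norm_dir <- function(v, name) {
    v <- as.numeric(v)
    if (length(v) != 3 || any(!is.finite(v)) || all(v == 0))
      stop(name, " must be a finite nonzero length-3 vector")
    n <- sqrt(sum(v^2))
    if (abs(n - 1) > 1e-6) {
      warning(name, " is not unit length (|v| = ", format(n),
              "); normalizing", call. = FALSE)
      v <- v / n
    }
    v
  }
  apical_direction <- norm_dir(apical_direction, "apical_direction")
  mechano_direction <- norm_dir(mechano_direction, "mechano_direction")
  cosang <- abs(sum(apical_direction * mechano_direction))
  if (cosang > cos(pi / 180))
    stop("apical_direction and mechano_direction are parallel within 1 degree")

  if (!is.data.frame(label_table) ||
      !all(c("label", "bundle", "row") %in% names(label_table)))
    stop("label_table must have columns label, bundle, row")
  if (!all(label_table$row %in% ROW_LEVELS))
    stop("label_table$row values must be one of: ",
         paste(ROW_LEVELS, collapse = ", "))
  present <- sort(unique(as.vector(cilium_labels)))
  present <- present[present != 0]
  missing <- setdiff(present, label_table$label)
  if (length(missing))
    stop("label_table is missing volume label id(s): ",
         paste(missing, collapse = ", "))

  if (!is.null(beads)) {
    if (!identical(dim(beads), dim(cilium_labels)))
      stop("bead volume grid is not congruent with the label grid (",
           paste(dim(beads), collapse = "x"), " vs ",
           paste(dim(cilium_labels), collapse = "x"), ")")
  }
  if (!is.null(bead_centroids)) {
    bead_centroids <- validate_bead_table(bead_centroids, dim(cilium_labels),
                                          spacing_nm)
  }

  structure(list(cilium_labels = cilium_labels,
                 beads = beads,
                 bead_centroids = bead_centroids,
                 spacing_nm = spacing_nm,
                 apical_direction = apical_direction,
                 mechano_direction = mechano_direction,
                 label_table = label_table),
            class = "annotated_volume")
}

#' @export
print.annotated_volume <- function(x, ...) {
  d <- dim(x$cilium_labels)
  cat("annotated_volume:", paste(d, collapse = " x "), "voxels (z y x),",
      "spacing", paste(x$spacing_nm, collapse = "/"), "nm\n")
  cat("  labels:", nrow(x$label_table), " beads:",
      if (!is.null(x$bead_centroids)) paste(nrow(x$bead_centroids), "centroids")
      else if (!is.null(x$beads)) "volume" else "none", "\n")
  invisible(x)
}

validate_bead_table <- function(tab, vol_dim = NULL, spacing_nm = NULL) {
  need <- c("bead_id", "z_nm", "y_nm", "x_nm")
  if (!is.data.frame(tab) || !all(need %in% names(tab)))
    stop("bead centroid table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$bead_id)) stop("bead_id values must be unique")
  coords <- as.matrix(tab[, c("z_nm", "y_nm", "x_nm")])
  if (any(!is.finite(coords))) stop("bead centroid coordinates must be finite")
  if (!is.null(vol_dim) && nrow(tab)) {
    upper <- (vol_dim - 1) * spacing_nm
    outside <- coords[, 1] < 0 | coords[, 2] < 0 | coords[, 3] < 0 |
      coords[, 1] > upper[1] | coords[, 2] > upper[2] | coords[, 3] > upper[3]
    if (any(outside))
      warning(sum(outside), " bead centroid(s) outside the volume bounding box",
              call. = FALSE)
  }
  tab
}

#' Read an annotated volume from TIFF stacks + JSON metadata
#'
#' @param label_path multi-page TIFF of integer cilium labels
#' @param bead_path bead observations: either a multi-page TIFF mask/label
#'   volume congruent with the labels, or a CSV centroid table
#'   (`bead_id,z_nm,y_nm,x_nm`); `NULL` for none
#' @param metadata_path JSON sidecar with keys `spacing_nm` (z, y, x),
#'   `apical_direction`, `mechano_direction`, `labels` (map label id ->
#'   `{bundle, row}`)
#' @return validated [annotated_volume()]
#' @export
read_annotated_volume <- function(label_path, bead_path = NULL, metadata_path) {
  for (p in c(label_path, metadata_path))
    if (!file.exists(p)) stop("file not found: ", p)
  meta <- jsonlite::fromJSON(metadata_path, simplifyVector = TRUE)
  for (key in c("spacing_nm", "apical_direction", "mechano_direction", "labels"))
    if (is.null(meta[[key]]))
      stop("metadata is missing required key '", key, "'")

  labels <- read_tiff_stack(label_path)
  lt <- meta$labels
  label_table <- data.frame(
    label = as.integer(names(lt)),
    bundle = vapply(lt, function(e) as.character(e$bundle), character(1)),
    row = vapply(lt, function(e) as.character(e$row), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  beads <- NULL; bead_centroids <- NULL
  if (!is.null(bead_path)) {
    if (!file.exists(bead_path)) stop("file not found: ", bead_path)
    if (grepl("\\.csv$", bead_path, ignore.case = TRUE)) {
      bead_centroids <- utils::read.csv(bead_path)
    } else {
      beads <- read_tiff_stack(bead_path)
    }
  }
  annotated_volume(labels, meta$spacing_nm, meta$apical_direction,
                   meta$mechano_direction, label_table,
                   beads = beads, bead_centroids = bead_centroids)
}

#' Write an annotated volume to TIFF stacks + JSON metadata
#'
#' Inverse of [read_annotated_volume()]; bead centroids (if any) go to a CSV
#' next to the other files.
#'
#' @param vol an [annotated_volume()]
#' @param dir output directory (created if needed)
#' @param basename file stem, default `"volume"`
#' @return named list of written paths, invisibly
#' @export
write_annotated_volume <- function(vol, dir, basename = "volume") {
  stopifnot(inherits(vol, "annotated_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  paths$labels <- file.path(dir, paste0(basename, "_labels.tif"))
  write_tiff_stack(vol$cilium_labels, paths$labels, bits = 16L)
  if (!is.null(vol$beads)) {
    paths$beads <- file.path(dir, paste0(basename, "_beads.tif"))
    write_tiff_stack(vol$beads, paths$beads, bits = 16L)
  }
  if (!is.null(vol$bead_centroids)) {
    paths$bead_centroids <- file.path(dir, paste0(basename, "_bead_centroids.csv"))
    utils::write.csv(vol$bead_centroids, paths$bead_centroids, row.names = FALSE)
  }
  labels_meta <- lapply(seq_len(nrow(vol$label_table)), function(i)
    list(bundle = vol$label_table$bundle[i], row = vol$label_table$row[i]))
  names(labels_meta) <- vol$label_table$label
  meta <- list(spacing_nm = vol$spacing_nm,
               apical_direction = vol$apical_direction,
               mechano_direction = vol$mechano_direction,
               labels = labels_meta)
  paths$metadata <- file.path(dir, paste0(basename, "_meta.json"))
  jsonlite::write_json(meta, paths$metadata, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Physical coordinates (nm) of all voxels carrying a given label
#'
#' 0-based voxel-center convention: voxel (k, j, i) maps to
#' (k*sz, j*sy, i*sx) nm.
#'
#' @param volume integer array `[z, y, x]`
#' @param label label id (or `NULL` for all nonzero voxels)
#' @param spacing_nm voxel spacing `(sz, sy, sx)`
#' @return n x 3 matrix of nm coordinates, columns z/y/x
#' @export
voxel_coords_nm <- function(volume, label = NULL, spacing_nm) {
  idx <- if (is.null(label)) which(volume != 0) else which(volume == label)
  idx_to_nm(idx, dim(volume), spacing_nm)
}

idx_to_nm <- function(idx, vol_dim, spacing_nm) {
  sub <- arrayInd(idx, vol_dim) - 1L   # 0-based (k, j, i)
  cbind(z = sub[, 1] * spacing_nm[1],
        y = sub[, 2] * spacing_nm[2],
        x = sub[, 3] * spacing_nm[3])
}

#' Write a density map to CSV
#'
#' Long format, one row per (row, segment, sector) bin with the bin count,
#' the number of overlaid cilia, the sector area and the resulting density in
#' beads per um^2 per cilium. Round-trips exactly through
#' [read_density_map()].
#'
#' @param map a `density_map` (see [compute_density_map()])
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_density_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  df <- as.data.frame(map)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Flatten a density map to a long data.frame
#' @param x a `density_map`
#' @param ... unused
#' @export
as.data.frame.density_map <- function(x, ...) {
  out <- do.call(rbind, lapply(names(x$rows), function(rw) {
    r <- x$rows[[rw]]
    if (r$n_segments == 0) return(NULL)
    grid <- expand.grid(segment_index = seq_len(r$n_segments) - 1L,
                        sector = SECTOR_LEVELS, stringsAsFactors = FALSE)
    data.frame(row = rw,
               segment_index = grid$segment_index,
               sector = grid$sector,
               count = as.vector(r$counts[cbind(grid$segment_index + 1L,
                                                match(grid$sector, SECTOR_LEVELS))]),
               n_cilia = r$n_cilia,
               sector_area_um2 = r$sector_area_um2,
               density_beads_per_um2 = as.vector(
                 r$density[cbind(grid$segment_index + 1L,
                                 match(grid$sector, SECTOR_LEVELS))]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(row = character(), segment_index = integer(),
                      sector = character(), count = integer(),
                      n_cilia = integer(), sector_area_um2 = numeric(),
                      density_beads_per_um2 = numeric())
  out
}

#' Read a density map CSV written by [write_density_map()]
#' @param path CSV path
#' @return a `density_map`
#' @export
read_density_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("row", "segment_index", "sector", "count", "n_cilia",
            "sector_area_um2", "density_beads_per_um2")
  if (!all(need %in% names(df)))
    stop("density map CSV must have columns ", paste(need, collapse = ", "))
  rows <- lapply(split(df, df$row), function(d) {
    n_seg <- max(d$segment_index) + 1L
    counts <- matrix(0, n_seg, 4, dimnames = list(NULL, SECTOR_LEVELS))
    density <- counts
    ij <- cbind(d$segment_index + 1L, match(d$sector, SECTOR_LEVELS))
    counts[ij] <- d$count
    density[ij] <- d$density_beads_per_um2
    list(n_segments = n_seg, counts = counts, density = density,
         sector_area_um2 = d$sector_area_um2[1], n_cilia = d$n_cilia[1])
  })
  structure(list(rows = rows), class = "density_map")
}
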