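# Bead reduction and projection: gold beads are reduced to centroids of
# their 26-connected components, then each centroid is assigned to a cilium
# by majority vote among its k nearest surface points (k = 10 by default)
# and dropped when it lies more than 100 nm from the winning cilium's
# surface.

#' Reduce a bead mask/label volume to centroids
#'
#' Finds 26-connected components of the nonzero voxels and returns each
#' component's centroid (unweighted mean of voxel centers) in nm.
#'
#' @param bead_volume integer/logical array `[z, y, x]`; nonzero = bead
#' @param spacing_nm voxel spacing `(sz, sy, sx)` in nm
#' @param min_voxels drop components smaller than this (default 1 = keep all)
#' @return data.frame `bead_id, z_nm, y_nm, x_nm, n_voxels`; empty for an
#'   empty mask
#' @export
compute_bead_centroids <- function(bead_volume, spacing_nm, min_voxels = 1L) {
  stopifnot(length(dim(bead_volume)) == 3)
  d <- dim(bead_volume)
  idx <- which(bead_volume != 0)
  if (!length(idx))
    return(data.frame(bead_id = integer(), z_nm = numeric(), y_nm = numeric(),
                      x_nm = numeric(), n_voxels = integer()))
  # union-find over foreground voxels, probing the 26-neighborhood through a
  # linear-index hash (environment); sparse masks only, by construction
  pos <- new.env(hash = TRUE, size = length(idx) * 2L)
  for (i in seq_along(idx)) assign(as.character(idx[i]), i, envir = pos)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  sub <- arrayInd(idx, d)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # only forward offsets needed (symmetry)
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE]
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(sub, 2, offs[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] + nb[ok, 1]
    src <- which(ok)
    for (m in seq_along(src)) {
      j <- pos[[as.character(nb_lin[m])]]
      if (!is.null(j)) {
        ri <- find(src[m]); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_along(idx), find, integer(1))
  comp <- match(root, unique(root))
  coords <- idx_to_nm(idx, d, spacing_nm)
  sizes <- tabulate(comp)
  cz <- tapply(coords[, 1], comp, mean)
  cy <- tapply(coords[, 2], comp, mean)
  cx <- tapply(coords[, 3], comp, mean)
  out <- data.frame(bead_id = seq_along(sizes), z_nm = as.numeric(cz),
                    y_nm = as.numeric(cy), x_nm = as.numeric(cx),
                    n_voxels = sizes)
  out <- out[out$n_voxels >= min_voxels, , drop = FALSE]
  out$bead_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Project bead centroids onto the nearest cilium surface (kNN vote)
#'
#' For each centroid the k nearest points of the pooled surface cloud (all
#' cilia together) are found; the bead is assigned to the cilium owning the
#' majority of those k points (ties go to the cilium owning the single
#' nearest point). The bead's surface point is the nearest surface point of
#' the winning cilium; beads farther than `cutoff_nm` from it are discarded.
#'
#' @param centroids data.frame `bead_id, z_nm, y_nm, x_nm`
#' @param geometries list of `cilium_geometry` (pooled surface cloud source)
#' @param k number of neighbors in the vote (default 10)
#' @param cutoff_nm discard distance (default 100)
#' @return data.frame of class `projected_beads`: `bead_id, cilium_id,
#'   distance_nm, nearest_distance_nm, surface_z_nm, surface_y_nm,
#'   surface_x_nm, discarded, reason`; `cilium_id` is NA for discarded beads
#' @export
project_beads <- function(centroids, geometries, k = 10L, cutoff_nm = 100) {
  centroids <- validate_bead_table(centroids)
  owners <- unlist(lapply(geometries, function(g)
    rep(g$cilium_id, nrow(g$surface_points))))
  cloud <- do.call(rbind, lapply(geometries, function(g) g$surface_points))
  if (is.null(cloud) || nrow(cloud) == 0) stop("pooled surface cloud is empty")
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(cloud))
    stop("k = ", k, " exceeds the pooled surface cloud size (", nrow(cloud), ")")
  n <- nrow(centroids)
  out <- data.frame(bead_id = centroids$bead_id,
                    cilium_id = rep(NA_integer_, n),
                    distance_nm = NA_real_, nearest_distance_nm = NA_real_,
                    surface_z_nm = NA_real_, surface_y_nm = NA_real_,
                    surface_x_nm = NA_real_,
                    discarded = logical(n), reason = NA_character_)
  if (!n) return(structure(out, class = c("projected_beads", "data.frame")))
  pts <- as.matrix(centroids[, c("z_nm", "y_nm", "x_nm")])
  chunk <- max(1L, floor(2e7 / nrow(cloud)))   # cap the distance matrix size
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    d2 <- dist2_matrix(pts[rows, , drop = FALSE], cloud)
    for (m in seq_along(rows)) {
      dd <- d2[m, ]
      nn <- order(dd)[seq_len(k)]
      votes <- table(owners[nn])
      winners <- names(votes)[votes == max(votes)]
      win <- if (length(winners) == 1L) winners else as.character(owners[nn[1]])
      sel <- owners == win
      j <- which(sel)[which.min(dd[sel])]
      dist_win <- sqrt(dd[j])
      i <- rows[m]
      out$nearest_distance_nm[i] <- sqrt(min(dd))
      out$distance_nm[i] <- dist_win
      out$surface_z_nm[i] <- cloud[j, 1]
      out$surface_y_nm[i] <- cloud[j, 2]
      out$surface_x_nm[i] <- cloud[j, 3]
      if (dist_win > cutoff_nm) {
        out$discarded[i] <- TRUE
        out$reason[i] <- "cutoff"
      } else {
        out$cilium_id[i] <- as.integer(win)
      }
    }
  }
  structure(out, class = c("projected_beads", "data.frame"))
}
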