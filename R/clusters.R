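# Neighbour offset table for 6/18/26 connectivity.
.conn_offsets <- function(connectivity) {
  stopifnot(connectivity %in% c(6, 18, 26))
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nrm <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = nrm == 1,
                 "18" = nrm >= 1 & nrm <= 2,
                 "26" = nrm >= 1)
  off[keep, , drop = FALSE]
}

# Label connected components of a logical 3D array by breadth-first search.
# Returns an integer array (0 = background), labels in first-encounter order.
.label_components <- function(supra, connectivity = 26) {
  d <- dim(supra)
  off <- .conn_offsets(connectivity)
  loff <- off %*% c(1, d[1], d[1] * d[2])
  # pad with a FALSE border so neighbour indexing never wraps across edges
  pd <- d + 2L
  padded <- array(FALSE, dim = pd)
  padded[2:(pd[1] - 1), 2:(pd[2] - 1), 2:(pd[3] - 1)] <- supra
  ploff <- off %*% c(1, pd[1], pd[1] * pd[2])
  labels_p <- integer(prod(pd))
  todo <- which(padded)
  lab <- 0L
  for (s in todo) {
    if (labels_p[s] != 0L) next
    lab <- lab + 1L
    frontier <- s
    labels_p[s] <- lab
    while (length(frontier) > 0) {
      nb <- unique(as.vector(outer(ploff[, 1], frontier, "+")))
      nb <- nb[padded[nb] & labels_p[nb] == 0L]
      labels_p[nb] <- lab
      frontier <- nb
    }
  }
  inner <- array(labels_p, dim = pd)[2:(pd[1] - 1), 2:(pd[2] - 1),
                                     2:(pd[3] - 1)]
  array(inner, dim = d)
}

#' Extract clusters from a suprathreshold map
#'
#' Finds connected components of the suprathreshold voxel set, drops
#' components whose volume is not strictly greater than
#' \code{min_volume_mm3}, determines which studies support each component
#' (a study supports a cluster when any of its foci lies within the kernel
#' truncation radius of any cluster voxel — the reach of its kernel mass),
#' and drops components supported by fewer than \code{min_study_support}
#' distinct studies. Remaining clusters are sorted by volume, descending.
#'
#' @param supra Logical suprathreshold 3D array.
#' @param grid An \code{ale_grid}.
#' @param joint Joint likelihood map, used to locate each cluster's peak.
#' @param foci Normalized foci data frame (for study support).
#' @param kernel An \code{ale_kernel} (its truncation radius defines the
#'   support reach).
#' @param connectivity 6, 18, or 26 (default 26).
#' @param min_volume_mm3 Strict volume floor (default 100).
#' @param min_study_support Minimum distinct supporting studies (default 2;
#'   single-study clusters are not reported).
#' @return List of clusters. Each has \code{id}, \code{voxels} (n x 3 index
#'   matrix), \code{n_voxels}, \code{volume_mm3}, \code{peak_mm},
#'   \code{center_mm} (center of mass), and \code{support} (data frame of
#'   supporting study_id/condition pairs). Attribute \code{label_map} holds
#'   the relabelled (post-filter) integer cluster map.
#' @export
extract_clusters <- function(supra, grid, joint, foci, kernel,
                             connectivity = 26, min_volume_mm3 = 100,
                             min_study_support = 2) {
  voxvol <- grid$voxel_mm^3
  stopifnot(min_volume_mm3 >= voxvol)
  labels <- .label_components(supra, connectivity)
  nlab <- max(labels)
  out <- list()
  for (l in seq_len(nlab)) {
    lin <- which(labels == l)
    vol <- length(lin) * voxvol
    if (vol <= min_volume_mm3) next
    vox <- arrayInd(lin, grid$dim)
    mm <- vox2mm(grid, vox)
    support <- .cluster_support(mm, foci, kernel$trunc_mm)
    if (length(unique(support$study_id)) < min_study_support) next
    vals <- joint[lin]
    peak <- mm[which.max(vals), ]
    com <- colSums(mm * vals) / sum(vals)
    out[[length(out) + 1]] <- list(
      voxels = vox, n_voxels = length(lin), volume_mm3 = vol,
      peak_mm = as.numeric(peak), center_mm = as.numeric(com),
      support = support)
  }
  if (length(out) > 0)
    out <- out[order(vapply(out, `[[`, numeric(1), "volume_mm3"),
                     decreasing = TRUE)]
  label_map <- array(0L, dim = grid$dim)
  for (i in seq_along(out)) {
    out[[i]]$id <- i
    label_map[out[[i]]$voxels] <- i
  }
  attr(out, "label_map") <- label_map
  out
}

# Studies whose foci reach the cluster: any focus within `radius_mm` of any
# cluster voxel center.
.cluster_support <- function(cluster_mm, foci, radius_mm) {
  if (nrow(foci) == 0)
    return(data.frame(study_id = character(), condition = character()))
  fx <- as.matrix(foci[, c("x", "y", "z")])
  r2 <- radius_mm^2
  near <- logical(nrow(fx))
  for (i in seq_len(nrow(fx))) {
    d2 <- (cluster_mm[, 1] - fx[i, 1])^2 + (cluster_mm[, 2] - fx[i, 2])^2 +
      (cluster_mm[, 3] - fx[i, 3])^2
    near[i] <- any(d2 <= r2)
  }
  unique(data.frame(study_id = foci$study_id[near],
                    condition = foci$condition[near]))
}
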