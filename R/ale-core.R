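#' Gaussian kernel specification
#'
#' The ALE kernel: an isotropic trivariate Gaussian placed on each focus,
#' parameterised by its full width at half maximum. The per-voxel
#' probability is the density at the voxel center times the voxel volume,
#' truncated to zero beyond \code{trunc_sd} standard deviations (default 4,
#' < 1e-4 relative mass loss).
#'
#' @param fwhm_mm Full width at half maximum in mm (default 8, the standard
#'   smoothing for grey-matter VBM meta-analysis).
#' @param trunc_sd Truncation radius in units of sigma (>= 3).
#' @return An object of class \code{ale_kernel} with fields \code{fwhm_mm},
#'   \code{sigma_mm} and \code{trunc_mm}.
#' @export
kernel_spec <- function(fwhm_mm = 8, trunc_sd = 4) {
  stopifnot(fwhm_mm > 0, trunc_sd >= 3)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  structure(list(fwhm_mm = fwhm_mm, sigma_mm = sigma,
                 trunc_mm = trunc_sd * sigma),
            class = "ale_kernel")
}

#' Kernel probability at a distance
#'
#' Probability contributed by a focus to a voxel at Euclidean distance
#' \code{d_mm}: the isotropic trivariate Gaussian density at that distance
#' times the voxel volume, clamped to [0, 1], and zero at or beyond the
#' truncation radius.
#'
#' @param d_mm Euclidean distance(s) in mm (vectorised).
#' @param kernel An \code{ale_kernel}.
#' @param voxel_volume_mm3 Voxel volume in cubic mm.
#' @return Probabilities in [0, 1].
#' @export
kernel_prob <- function(d_mm, kernel, voxel_volume_mm3) {
  s <- kernel$sigma_mm
  p <- voxel_volume_mm3 * (2 * pi * s^2)^(-3 / 2) * exp(-d_mm^2 / (2 * s^2))
  p[d_mm >= kernel$trunc_mm] <- 0
  pmin(pmax(p, 0), 1)
}

# Per-focus log-survival accumulation: adds log(1 - p) of one focus (at mm
# position fx) into the 3D array `logq` over the voxels inside the
# truncation sphere. Shared by study_map and the simulator-free brute path.
.accumulate_focus <- function(logq, grid, kernel, fx) {
  r <- kernel$trunc_mm
  vox <- grid$voxel_mm
  lo <- pmax(ceiling((fx - r - grid$origin) / vox) + 1, 1)
  hi <- pmin(floor((fx + r - grid$origin) / vox) + 1, grid$dim)
  if (any(lo > hi)) return(logq)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  dx2 <- (grid$origin[1] + (ix - 1) * vox - fx[1])^2
  dy2 <- (grid$origin[2] + (iy - 1) * vox - fx[2])^2
  dz2 <- (grid$origin[3] + (iz - 1) * vox - fx[3])^2
  d <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  p <- kernel_prob(d, kernel, vox^3)
  logq[ix, iy, iz] <- logq[ix, iy, iz] + log1p(-p)
  logq
}

#' Per-study likelihood map
#'
#' Builds one study's likelihood map: each focus contributes a truncated
#' Gaussian probability field, and per voxel the study map is the
#' probability that at least one focus "hits" the voxel,
#' \deqn{1 - \prod_i (1 - p_i(v)),} the union of the per-focus events.
#' Voxels outside the brain mask are zero.
#'
#' @param foci Data frame with numeric \code{x}, \code{y}, \code{z} (mm, in
#'   the working Talairach space); one row per focus of a single study (and
#'   single condition/direction).
#' @param grid An \code{ale_grid}.
#' @param kernel An \code{ale_kernel}.
#' @param mask Logical 3D array on the grid, or \code{NULL} for no masking.
#' @return 3D array of per-voxel probabilities in [0, 1].
#' @export
study_map <- function(foci, grid, kernel, mask = NULL) {
  if (nrow(foci) == 0) stop("study has no foci")
  logq <- array(0, dim = grid$dim)
  xyz <- as.matrix(foci[, c("x", "y", "z")])
  for (i in seq_len(nrow(xyz)))
    logq <- .accumulate_focus(logq, grid, kernel, xyz[i, ])
  m <- -expm1(logq)
  if (!is.null(mask)) m[!mask] <- 0
  m
}

#' Condition mean likelihood map
#'
#' Voxelwise arithmetic mean of the per-study likelihood maps of one
#' condition. Averaging (rather than pooling foci) keeps the condition with
#' more reported foci from dominating the joint map.
#'
#' @param maps List of 3D study-map arrays on a common grid.
#' @return 3D array of voxelwise means.
#' @export
condition_mean_map <- function(maps) {
  stopifnot(length(maps) >= 1)
  d <- dim(maps[[1]])
  for (m in maps)
    if (!identical(dim(m), d)) stop("study maps are on different grids")
  Reduce(`+`, maps) / length(maps)
}

#' Joint likelihood map
#'
#' Voxelwise sum of the two condition mean maps. Values lie in [0, 2].
#'
#' @param mean_a,mean_b Condition mean maps on a common grid.
#' @return 3D array, the joint likelihood map.
#' @export
joint_map <- function(mean_a, mean_b) {
  if (!identical(dim(mean_a), dim(mean_b)))
    stop("condition mean maps are on different grids")
  mean_a + mean_b
}

#' Condition mean maps from a foci table
#'
#' Convenience wrapper: splits a (normalized, single-direction) foci table
#' into per-study groups, builds each study map, and averages within each
#' condition.
#'
#' @param foci Normalized foci data frame (single direction).
#' @param grid,kernel,mask As in [study_map()].
#' @param conditions Ordered pair of condition labels; defaults to the
#'   sorted labels present.
#' @return Named list of condition mean maps (3D arrays) plus attribute
#'   \code{n_studies} (per-condition study counts).
#' @export
condition_maps <- function(foci, grid, kernel, mask = NULL,
                           conditions = NULL) {
  if (is.null(conditions)) conditions <- sort(unique(foci$condition))
  out <- list()
  nst <- integer(length(conditions))
  names(nst) <- conditions
  for (cd in conditions) {
    sub <- foci[foci$condition == cd, , drop = FALSE]
    if (nrow(sub) == 0) stop("condition has no foci: ", cd)
    groups <- split(sub, sub$study_id, drop = TRUE)
    maps <- lapply(groups, study_map, grid = grid, kernel = kernel,
                   mask = mask)
    nst[cd] <- length(maps)
    out[[cd]] <- condition_mean_map(maps)
  }
  attr(out, "n_studies") <- nst
  out
}
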