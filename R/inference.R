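# Precomputes the kernel's voxel-centered probability cube: relative integer
# offsets within the truncation sphere and log(1 - p) at each. Every focus
# relocated to a voxel center in the permutation null shares this one cube,
# which is what makes the null loop cheap.
.kernel_cube <- function(grid, kernel) {
  vox <- grid$voxel_mm
  r <- as.integer(ceiling(kernel$trunc_mm / vox))
  off <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  d <- vox * sqrt(rowSums(off^2))
  p <- kernel_prob(d, kernel, vox^3)
  keep <- p > 0
  list(r = r, off = off[keep, , drop = FALSE], logq = log1p(-p[keep]))
}

#' Permutation null distribution of the joint likelihood map
#'
#' Samples the null hypothesis of no spatial association between studies:
#' in each permutation every focus is relocated to an independent
#' uniform-random in-mask voxel center, the per-study and per-condition
#' grouping is preserved, and the full study -> condition-mean -> joint
#' pipeline is recomputed. All in-mask joint values of all permutations are
#' pooled into one fixed-bin histogram over [0, 2].
#'
#' @param foci Normalized foci data frame (single direction, two
#'   conditions).
#' @param grid,kernel,mask As in [study_map()]; \code{mask} is required.
#' @param n_permutations Number of permutations (>= 100 for any inferential
#'   run; the published protocol uses 10,000).
#' @param seed Integer seed; recorded in the result.
#' @param n_bins Histogram resolution (default 32768 bins on [0, 2]).
#' @param conditions Ordered condition labels (default: sorted labels
#'   present).
#' @return An object of class \code{ale_null}: bin counts, bin width, total
#'   pooled value count, permutation count and seed.
#' @export
permutation_null <- function(foci, grid, kernel, mask, n_permutations = 10000,
                             seed = 1L, n_bins = 32768L, conditions = NULL) {
  stopifnot(n_permutations >= 1)
  if (is.null(mask) || !any(mask)) stop("permutation null requires a non-empty mask")
  if (is.null(conditions)) conditions <- sort(unique(foci$condition))
  stopifnot(length(conditions) == 2)

  cube <- .kernel_cube(grid, kernel)
  r <- cube$r
  pd <- grid$dim + 2L * r                     # padded dims
  noff <- cube$off %*% c(1, pd[1], pd[1] * pd[2])  # linear offsets, padded
  mask_lin <- which(mask)                     # unpadded linear indices
  ijk <- arrayInd(mask_lin, grid$dim)
  pad_lin <- as.vector((ijk + r - 1) %*% c(1, pd[1], pd[1] * pd[2])) + 1L
  inv_pad <- integer(prod(pd))                # padded linear -> mask rank
  inv_pad[pad_lin] <- seq_along(pad_lin)

  # per-study focus counts, grouped by condition
  counts <- lapply(conditions, function(cd) {
    sub <- foci[foci$condition == cd, , drop = FALSE]
    if (nrow(sub) == 0) stop("condition has no foci: ", cd)
    as.integer(table(sub$study_id))
  })

  set.seed(seed)
  width <- 2 / n_bins
  hist_counts <- numeric(n_bins)
  logq <- numeric(prod(pd))
  n_mask <- length(mask_lin)
  joint <- numeric(n_mask)

  for (perm in seq_len(n_permutations)) {
    joint[] <- 0
    for (ci in 1:2) {
      nstud <- length(counts[[ci]])
      acc <- numeric(n_mask)
      for (k in counts[[ci]]) {
        centers <- pad_lin[sample.int(n_mask, k, replace = TRUE)]
        touched <- vector("list", k)
        for (f in seq_len(k)) {             # indices unique within one focus
          idx <- centers[f] + noff[, 1]
          logq[idx] <- logq[idx] + cube$logq
          touched[[f]] <- idx
        }
        idx <- unique(unlist(touched, use.names = FALSE))
        hit <- inv_pad[idx]                 # 0 where outside the mask
        inm <- hit > 0L
        acc[hit[inm]] <- acc[hit[inm]] - expm1(logq[idx[inm]])
        logq[idx] <- 0
      }
      joint <- joint + acc / nstud
    }
    b <- pmin(floor(joint / width) + 1, n_bins)
    b <- b[joint > 0]
    if (length(b) > 0) {
      tb <- tabulate(b, nbins = n_bins)
      hist_counts <- hist_counts + tb
    }
    hist_counts[1] <- hist_counts[1] + (n_mask - length(b))  # zeros
  }

  structure(list(counts = hist_counts, width = width, n_bins = n_bins,
                 n_values = n_mask * n_permutations,
                 n_permutations = n_permutations, seed = seed),
            class = "ale_null")
}

#' @export
print.ale_null <- function(x, ...) {
  cat(sprintf("ALE permutation null: %d permutations, %g pooled values, seed %d\n",
              x$n_permutations, x$n_values, x$seed))
  invisible(x)
}

#' Voxelwise permutation p-values
#'
#' Per voxel, the add-one permutation p-value
#' \deqn{p = (1 + \#\{null \ge observed\}) / (1 + N).}
#' The null may be an \code{ale_null} pooled histogram (values falling in
#' the observed value's bin count as >= observed, a conservative tie rule)
#' or a raw numeric vector of null values (exact counting).
#'
#' @param joint Observed joint likelihood map (3D array) or numeric vector.
#' @param null An \code{ale_null} or a numeric vector.
#' @param mask Optional logical array; out-of-mask voxels get p = 1.
#' @return Array (or vector) of p-values in (0, 1].
#' @export
voxel_pvalues <- function(joint, null, mask = NULL) {
  obs <- as.numeric(joint)
  if (inherits(null, "ale_null")) {
    n <- null$n_values
    tail_ge <- rev(cumsum(rev(null$counts)))  # count in bins >= b
    b <- pmin(pmax(floor(obs / null$width) + 1, 1), null$n_bins)
    cnt <- tail_ge[b]
    cnt[obs <= 0] <- n  # everything is >= a non-positive observation
  } else {
    nullv <- as.numeric(null)
    stopifnot(length(nullv) > 0)
    n <- length(nullv)
    srt <- sort(nullv)
    cnt <- n - findInterval(obs, srt, left.open = TRUE)
  }
  p <- (1 + cnt) / (1 + n)
  if (!is.null(dim(joint))) {
    p <- array(p, dim = dim(joint))
    if (!is.null(mask)) p[!mask] <- 1
  }
  p
}

#' Benjamini-Hochberg FDR threshold
#'
#' Applies the BH step-up rule over all in-mask voxels at rate \code{q}:
#' with ordered p-values, the largest k with \eqn{p_{(k)} \le k q / m}
#' defines the cutoff, and all voxels with \eqn{p \le p_{(k)}} are
#' suprathreshold. Retains nothing when no such k exists.
#'
#' @param p P-value map (3D array).
#' @param q FDR level (default 0.05).
#' @param mask Logical array restricting the voxel family; default all.
#' @return Logical suprathreshold array of the same dimension.
#' @export
fdr_threshold <- function(p, q = 0.05, mask = NULL) {
  stopifnot(q > 0, q < 1)
  supra <- array(FALSE, dim = dim(p))
  idx <- if (is.null(mask)) seq_along(p) else which(mask)
  padj <- stats::p.adjust(p[idx], method = "BH")
  supra[idx] <- padj <= q
  supra
}
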