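#' Brett mni2tal transform
#'
#' Maps MNI mm coordinates to Talairach mm coordinates using Matthew Brett's
#' piecewise-linear approximation. The branch is selected on the sign of the
#' input MNI z coordinate (z >= 0 uses the "above-AC" matrix).
#'
#' @param p Numeric vector of length 3 (x, y, z in mm), or an n x 3 matrix of
#'   coordinates (one row per point).
#' @return Transformed coordinates with the same shape as the input.
#' @seealso [brett_tal2mni()], [lancaster_icbm2tal()]
#' @export
#' @examples
#' brett_mni2tal(c(10, 12, 8))
brett_mni2tal <- function(p) {
  p <- .as_coord_matrix(p)
  up <- p[, 3] >= 0
  out <- p
  if (any(up)) out[up, ] <- p[up, , drop = FALSE] %*% t(.BRETT_UP)
  if (any(!up)) out[!up, ] <- p[!up, , drop = FALSE] %*% t(.BRETT_DOWN)
  .restore_coord_shape(out, p)
}

#' Brett tal2mni transform
#'
#' Exact functional inverse of [brett_mni2tal()]. The z >= 0 branch inverse
#' is tried first and accepted when its image has nonnegative z; because the
#' two Brett branch matrices share their x and y columns, the sign of that
#' candidate z equals the sign of the original MNI z, so round trips are
#' exact on both branches.
#'
#' @inheritParams brett_mni2tal
#' @return MNI mm coordinates with the same shape as the input.
#' @export
brett_tal2mni <- function(p) {
  p <- .as_coord_matrix(p)
  cand <- p %*% t(.BRETT_UP_INV)
  down <- cand[, 3] < 0
  if (any(down)) cand[down, ] <- p[down, , drop = FALSE] %*% t(.BRETT_DOWN_INV)
  .restore_coord_shape(cand, p)
}

#' Lancaster icbm2tal transform
#'
#' Single affine map from ICBM-152/MNI mm coordinates to Talairach mm
#' coordinates (Lancaster et al. 2007). The \code{"spm"} variant
#' (icbm_spm2tal, for SPM-normalised data) is the package default; the
#' \code{"fsl"} variant (icbm_fsl2tal) is available for FSL-normalised data.
#'
#' @inheritParams brett_mni2tal
#' @param variant \code{"spm"} (default) or \code{"fsl"}.
#' @return Talairach mm coordinates with the same shape as the input.
#' @export
#' @examples
#' lancaster_icbm2tal(c(0, 0, 0))  # the matrix translation column
lancaster_icbm2tal <- function(p, variant = c("spm", "fsl")) {
  variant <- match.arg(variant)
  p <- .as_coord_matrix(p)
  m <- .LANCASTER[[variant]]
  out <- cbind(p, 1) %*% t(m[1:3, ])
  .restore_coord_shape(out, p)
}

#' Normalize foci coordinates into native Talairach space
#'
#' Every focus is brought into the single working space (Talairach) of the
#' analysis. \code{TAL_NATIVE} coordinates pass through unchanged. \code{MNI}
#' coordinates receive the Lancaster icbm2tal affine. \code{TAL_BRETT}
#' coordinates (Talairach obtained originally with Brett's mni2tal) are first
#' returned to MNI with the exact Brett inverse and then mapped with
#' icbm2tal, so every focus ends up on the same Lancaster-defined Talairach
#' frame.
#'
#' @param foci A foci data frame as returned by [parse_foci_table()] (or any
#'   data frame with numeric \code{x}, \code{y}, \code{z} and a \code{space}
#'   column).
#' @param variant Lancaster matrix variant, see [lancaster_icbm2tal()].
#' @return The data frame with coordinates transformed and \code{space} set
#'   to \code{"TAL_NATIVE"} on every row.
#' @export
normalize_space <- function(foci, variant = c("spm", "fsl")) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(foci), all(c("x", "y", "z", "space") %in% names(foci)))
  bad <- setdiff(unique(foci$space), .SPACES)
  if (length(bad) > 0)
    stop("unknown coordinate space tag(s): ", paste(bad, collapse = ", "))
  xyz <- as.matrix(foci[, c("x", "y", "z")])
  is_mni <- foci$space == "MNI"
  is_brett <- foci$space == "TAL_BRETT"
  if (any(is_brett))
    xyz[is_brett, ] <- brett_tal2mni(xyz[is_brett, , drop = FALSE])
  conv <- is_mni | is_brett
  if (any(conv))
    xyz[conv, ] <- lancaster_icbm2tal(xyz[conv, , drop = FALSE], variant)
  foci$x <- xyz[, 1]; foci$y <- xyz[, 2]; foci$z <- xyz[, 3]
  foci$space <- "TAL_NATIVE"
  .check_coord_bounds(foci)
  foci
}

.as_coord_matrix <- function(p) {
  if (is.null(dim(p))) {
    stopifnot(length(p) == 3)
    p <- matrix(as.numeric(p), nrow = 1)
    attr(p, "was_vector") <- TRUE
  } else {
    stopifnot(ncol(p) == 3)
    storage.mode(p) <- "double"
  }
  if (!all(is.finite(p))) stop("coordinates must be finite")
  p
}

.restore_coord_shape <- function(out, p) {
  if (isTRUE(attr(p, "was_vector"))) as.numeric(out) else out
}

.check_coord_bounds <- function(foci, bound = 120) {
  xyz <- as.matrix(foci[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates after transformation")
  if (any(abs(xyz) > bound))
    stop("coordinate magnitude exceeds the ", bound,
         " mm sanity bound; check for mm/voxel confusion")
  invisible(foci)
}
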