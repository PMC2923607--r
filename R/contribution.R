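#' Per-cluster condition contribution percentages
#'
#' The attribution statistic: for a retained cluster, each condition's
#' contribution is the intensity ratio of its mean likelihood map to the
#' joint map, integrated over the cluster's voxels:
#' \deqn{pct_A = 100 \cdot \frac{\sum_{v \in c} \bar{A}(v)}
#'   {\sum_{v \in c} (\bar{A}(v) + \bar{B}(v))}}
#' and analogously for B, so the two percentages always sum to 100. A
#' cluster formed purely by one condition's studies scores (100, 0); equal
#' mean intensity scores (50, 50), an equal chance that foci from either
#' condition formed the cluster. A \code{"peak"} variant evaluates the
#' ratio at the cluster's peak joint-likelihood voxel instead.
#'
#' @param cluster One cluster from [extract_clusters()].
#' @param mean_a,mean_b Condition mean maps (3D arrays on the cluster's
#'   grid), in the label order of the analysis.
#' @param method \code{"integrated"} (default) or \code{"peak"}.
#' @param grid Required for \code{method = "peak"} (to locate the peak
#'   voxel).
#' @return Named numeric vector \code{c(pct_a, pct_b)} in [0, 100].
#' @export
cluster_contribution <- function(cluster, mean_a, mean_b,
                                 method = c("integrated", "peak"),
                                 grid = NULL) {
  method <- match.arg(method)
  if (method == "integrated") {
    a <- sum(mean_a[cluster$voxels])
    b <- sum(mean_b[cluster$voxels])
  } else {
    stopifnot(!is.null(grid))
    pk <- mm2vox(grid, cluster$peak_mm)
    pk <- matrix(pk, nrow = 1)
    a <- mean_a[pk]
    b <- mean_b[pk]
  }
  tot <- a + b
  if (tot <= 0)
    stop("degenerate cluster: zero joint mass over its voxels")
  c(pct_a = 100 * a / tot, pct_b = 100 * b / tot)
}

#' Classify a cluster's attribution
#'
#' Presentation-layer classification of a contribution record into
#' condition-specific versus shared, mirroring the colour-coding convention
#' for joint ALE maps (one colour per dominant condition, a third for
#' clusters formed by both). A cluster is \code{SHARED} when both
#' percentages reach the band half-width; otherwise it belongs to the
#' dominant condition.
#'
#' @param pct Numeric vector \code{c(pct_a, pct_b)} summing to 100.
#' @param band Percentage half-width (default 20: 20-80\% counts as
#'   shared). The band is a display convention, not part of the statistic.
#' @return One of \code{"A_ONLY"}, \code{"B_ONLY"}, \code{"SHARED"}.
#' @export
attribution_class <- function(pct, band = 20) {
  stopifnot(length(pct) == 2, band >= 0, band <= 50)
  if (pct[1] >= band && pct[2] >= band) return("SHARED")
  if (pct[1] >= pct[2]) "A_ONLY" else "B_ONLY"
}

#' Contribution table for a set of clusters
#'
#' @param clusters List from [extract_clusters()].
#' @param means Named list of the two condition mean maps (label order
#'   preserved).
#' @param method Passed to [cluster_contribution()].
#' @param grid Passed to [cluster_contribution()].
#' @param band Passed to [attribution_class()].
#' @return Data frame with one row per cluster: id, center and peak
#'   coordinates, volume, per-condition supporting study counts, the two
#'   contribution percentages and the attribution class.
#' @export
contribution_table <- function(clusters, means,
                               method = c("integrated", "peak"),
                               grid = NULL, band = 20) {
  method <- match.arg(method)
  labels <- names(means)
  stopifnot(length(labels) == 2)
  rows <- lapply(clusters, function(cl) {
    pct <- cluster_contribution(cl, means[[1]], means[[2]], method, grid)
    supp <- table(factor(cl$support$condition, levels = labels))
    data.frame(
      cluster = cl$id,
      peak_x = cl$peak_mm[1], peak_y = cl$peak_mm[2], peak_z = cl$peak_mm[3],
      center_x = cl$center_mm[1], center_y = cl$center_mm[2],
      center_z = cl$center_mm[3],
      volume_mm3 = cl$volume_mm3,
      n_studies_a = as.integer(supp[[1]]), n_studies_b = as.integer(supp[[2]]),
      pct_a = pct[["pct_a"]], pct_b = pct[["pct_b"]],
      class = attribution_class(pct, band))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cluster = integer(), peak_x = numeric(),
                      peak_y = numeric(), peak_z = numeric(),
                      center_x = numeric(), center_y = numeric(),
                      center_z = numeric(), volume_mm3 = numeric(),
                      n_studies_a = integer(), n_studies_b = integer(),
                      pct_a = numeric(), pct_b = numeric(),
                      class = character())
  names(out)[names(out) == "n_studies_a"] <- paste0("n_studies_", labels[1])
  names(out)[names(out) == "n_studies_b"] <- paste0("n_studies_", labels[2])
  names(out)[names(out) == "pct_a"] <- paste0("pct_", labels[1])
  names(out)[names(out) == "pct_b"] <- paste0("pct_", labels[2])
  out
}
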