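#' Ground-truth effect center
#'
#' One "true" locus of grey-matter difference for the synthetic corpus
#' generator. Each study of condition i reports the center with probability
#' \code{prob[i]} (one focus per study and center), displaced by isotropic
#' Gaussian jitter emulating between-study spatial scatter.
#'
#' @param location mm triple (must be inside the analysis mask).
#' @param prob Length-2 report probabilities, one per condition (in the
#'   order of the corpus condition labels). \code{c(1, 0)} is a
#'   condition-A-only center; \code{c(1, 1)} a fully shared one.
#' @param jitter_sd Isotropic jitter SD in mm (default 6: of kernel order,
#'   above voxel size, below twice the FWHM).
#' @param direction Effect direction for foci of this center.
#' @param n_foci Foci emitted per reporting study (default 1). Values > 1
#'   emulate the multiple subpeaks studies report within a robustly
#'   affected region, i.e. a strong-signal center.
#' @return An \code{effect_center} object.
#' @export
effect_center <- function(location, prob, jitter_sd = 6,
                          direction = "DEFICIT", n_foci = 1L) {
  stopifnot(length(location) == 3, length(prob) == 2,
            all(prob >= 0), all(prob <= 1), jitter_sd >= 0,
            direction %in% .DIRECTIONS, n_foci >= 1)
  structure(list(location = as.numeric(location), prob = as.numeric(prob),
                 jitter_sd = jitter_sd, direction = direction,
                 n_foci = as.integer(n_foci)),
            class = "effect_center")
}

#' Default ground-truth configuration
#'
#' Emulates the corpus shape of a two-condition VBM meta-analysis: two
#' conditions with 15 and 10 studies, shared and condition-unique effect
#' centers, and uniform noise foci forcing the FDR and cluster-volume
#' filters to work. The defaults yield roughly 250-400 foci split about
#' 60/40 between conditions.
#'
#' @param n_studies Length-2 integer vector: studies per condition.
#' @param noise_range Min/max uniform noise foci per study.
#' @param centers List of [effect_center()] objects; the default places two
#'   shared, three condition-A-only and two condition-B-only deficit
#'   centers at plausible grey-matter Talairach locations.
#' @param conditions Ordered pair of condition labels.
#' @param seed Integer seed (mandatory for reproducibility).
#' @return A \code{sim_config} object.
#' @export
sim_config <- function(n_studies = c(15, 10), noise_range = c(4, 10),
                       centers = default_centers(), conditions = c("ASD", "SCZ"),
                       seed = 1L) {
  stopifnot(length(n_studies) == 2, all(n_studies >= 1),
            length(noise_range) == 2, noise_range[1] >= 0,
            noise_range[2] >= noise_range[1],
            length(conditions) == 2, !is.null(seed))
  structure(list(n_studies = as.integer(n_studies),
                 noise_range = as.integer(noise_range),
                 centers = centers, conditions = conditions,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_centers <- function() {
  list(
    effect_center(c(30, -16, -12), prob = c(0.9, 0.9)),   # shared
    effect_center(c(-8, -20, 10), prob = c(0.9, 0.9)),    # shared
    effect_center(c(-24, 2, 4), prob = c(0.9, 0)),        # A only
    effect_center(c(44, 30, 20), prob = c(0.9, 0)),       # A only
    effect_center(c(0, -44, 32), prob = c(0.9, 0)),       # A only
    effect_center(c(-38, 20, 0), prob = c(0, 0.9)),       # B only
    effect_center(c(22, -54, 14), prob = c(0, 0.9))       # B only
  )
}

#' Simulate a two-condition foci corpus with known ground truth
#'
#' Per study and effect center, a focus is emitted with the center's
#' per-condition report probability, displaced by isotropic Gaussian jitter
#' (redrawn until inside the mask), and uniform noise foci are added inside
#' the mask. The manifest attributes every emitted focus to exactly one
#' center or to noise.
#'
#' @param sc A \code{sim_config}.
#' @param grid An \code{ale_grid}.
#' @param mask Logical 3D array on the grid.
#' @return List with \code{foci} (an \code{ale_foci} data frame, all
#'   \code{TAL_NATIVE}) and \code{manifest} (one row per focus: study,
#'   condition, source \code{center_<k>} or \code{noise}, and the true
#'   center location for center foci).
#' @export
simulate_corpus <- function(sc, grid, mask) {
  if (is.null(mask) || !any(mask)) stop("simulation requires a non-empty mask")
  set.seed(sc$seed)
  mask_lin <- which(mask)
  mask_mm <- vox2mm(grid, arrayInd(mask_lin, grid$dim))
  in_mask <- function(p) {
    v <- mm2vox(grid, p)
    all(v >= 1) && all(v <= grid$dim) && mask[matrix(v, nrow = 1)]
  }
  rows <- list()
  emit <- function(study, cond, xyz, direction, source, center) {
    rows[[length(rows) + 1]] <<- data.frame(
      study_id = study, condition = cond, space = "TAL_NATIVE",
      x = xyz[1], y = xyz[2], z = xyz[3], direction = direction,
      source = source,
      true_x = center[1], true_y = center[2], true_z = center[3])
  }
  for (ci in 1:2) {
    cond <- sc$conditions[ci]
    for (s in seq_len(sc$n_studies[ci])) {
      study <- sprintf("%s_study%02d", cond, s)
      for (k in seq_along(sc$centers)) {
        ec <- sc$centers[[k]]
        if (stats::runif(1) >= ec$prob[ci]) next
        for (f in seq_len(ec$n_foci)) {
          repeat {
            p <- ec$location + stats::rnorm(3, 0, ec$jitter_sd)
            if (in_mask(p)) break
          }
          emit(study, cond, p, ec$direction, sprintf("center_%d", k),
               ec$location)
        }
      }
      n_noise <- sample(seq(sc$noise_range[1], sc$noise_range[2]), 1)
      for (j in seq_len(n_noise)) {
        v <- mask_mm[sample.int(nrow(mask_mm), 1), ]
        p <- v + stats::runif(3, -grid$voxel_mm / 2, grid$voxel_mm / 2)
        emit(study, cond, p, "DEFICIT", "noise", c(NA, NA, NA))
      }
    }
  }
  manifest <- do.call(rbind, rows)
  foci <- as_foci(manifest[, c("study_id", "condition", "space",
                               "x", "y", "z", "direction")])
  list(foci = foci, manifest = manifest)
}

#' Ground-truth recovery report
#'
#' Compares a pipeline run on a simulated corpus against the generator's
#' ground truth: for each effect center, whether a retained cluster lies
#' within \code{match_radius_mm}, the localization error, and the matched
#' cluster's contribution percentages next to the center's expected split
#' (derived from its per-condition report probabilities).
#'
#' @param result One direction's result from [run_analysis()] (or any list
#'   with a \code{table} contribution data frame).
#' @param sc The \code{sim_config} that generated the corpus.
#' @param match_radius_mm Matching radius (default 10).
#' @return Data frame, one row per effect center: center location, expected
#'   pct for condition A, matched cluster id (NA if unmatched),
#'   localization error in mm, and observed pct_a/pct_b.
#' @export
recovery_report <- function(result, sc, match_radius_mm = 10) {
  tab <- result$table
  pct_cols <- paste0("pct_", sc$conditions)
  rows <- lapply(seq_along(sc$centers), function(k) {
    ec <- sc$centers[[k]]
    expected <- if (sum(ec$prob) > 0) 100 * ec$prob[1] / sum(ec$prob) else NA_real_
    row <- data.frame(center = k,
                      x = ec$location[1], y = ec$location[2],
                      z = ec$location[3],
                      expected_pct_a = expected, cluster = NA_integer_,
                      error_mm = NA_real_, pct_a = NA_real_,
                      pct_b = NA_real_)
    if (nrow(tab) > 0) {
      d_peak <- sqrt((tab$peak_x - ec$location[1])^2 +
                     (tab$peak_y - ec$location[2])^2 +
                     (tab$peak_z - ec$location[3])^2)
      d_com <- sqrt((tab$center_x - ec$location[1])^2 +
                    (tab$center_y - ec$location[2])^2 +
                    (tab$center_z - ec$location[3])^2)
      d <- pmin(d_peak, d_com)
      i <- which.min(d)
      if (d[i] <= match_radius_mm) {
        row$cluster <- tab$cluster[i]
        row$error_mm <- d[i]
        row$pct_a <- tab[[pct_cols[1]]][i]
        row$pct_b <- tab[[pct_cols[2]]][i]
      }
    }
    row
  })
  do.call(rbind, rows)
}
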