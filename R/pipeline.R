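#' Analysis configuration
#'
#' Collects every tunable of the joint ALE pipeline. The defaults are the
#' published protocol constants: 8 mm FWHM kernel, 10,000 permutations,
#' FDR q = 0.05, cluster volume floor 100 mm^3, and single-study clusters
#' not reported.
#'
#' @param fwhm_mm Kernel FWHM in mm.
#' @param trunc_sd Kernel truncation radius in sigmas.
#' @param voxel_mm Isotropic grid voxel size in mm.
#' @param xlim,ylim,zlim Grid bounding box in Talairach mm.
#' @param n_permutations Permutations for the null distribution.
#' @param seed Integer seed for the permutation engine.
#' @param fdr_q FDR level.
#' @param min_cluster_volume_mm3 Strict cluster volume floor.
#' @param connectivity Cluster connectivity rule: 6, 18 or 26.
#' @param min_study_support Minimum distinct studies supporting a cluster.
#' @param conditions Ordered pair of condition labels, or \code{NULL} to
#'   take the sorted labels found in the foci table.
#' @param directions Effect directions to analyse (each in a fully
#'   independent run).
#' @param lancaster_variant Lancaster icbm2tal matrix variant
#'   (\code{"spm"} or \code{"fsl"}).
#' @param contribution_method \code{"integrated"} or \code{"peak"}.
#' @param shared_band Attribution classification half-width in percent.
#' @return An \code{ale_config} object (a validated named list).
#' @export
analysis_config <- function(fwhm_mm = 8, trunc_sd = 4, voxel_mm = 2,
                            xlim = c(-70, 70), ylim = c(-104, 68),
                            zlim = c(-50, 78),
                            n_permutations = 10000, seed = 1L,
                            fdr_q = 0.05, min_cluster_volume_mm3 = 100,
                            connectivity = 26, min_study_support = 2,
                            conditions = NULL,
                            directions = c("DEFICIT", "EXCESS"),
                            lancaster_variant = "spm",
                            contribution_method = "integrated",
                            shared_band = 20) {
  stopifnot(fwhm_mm > 0, n_permutations >= 1, fdr_q > 0, fdr_q < 1,
            connectivity %in% c(6, 18, 26), min_study_support >= 1,
            all(directions %in% .DIRECTIONS),
            lancaster_variant %in% c("spm", "fsl"),
            contribution_method %in% c("integrated", "peak"))
  cfg <- list(fwhm_mm = fwhm_mm, trunc_sd = trunc_sd, voxel_mm = voxel_mm,
              xlim = xlim, ylim = ylim, zlim = zlim,
              n_permutations = as.integer(n_permutations),
              seed = as.integer(seed), fdr_q = fdr_q,
              min_cluster_volume_mm3 = min_cluster_volume_mm3,
              connectivity = as.integer(connectivity),
              min_study_support = as.integer(min_study_support),
              conditions = conditions, directions = directions,
              lancaster_variant = lancaster_variant,
              contribution_method = contribution_method,
              shared_band = shared_band)
  class(cfg) <- "ale_config"
  cfg
}

#' Load an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [analysis_config()]; absent keys keep their
#' defaults. \code{overrides} accepts \code{"key=value"} strings (the CLI's
#' \code{--set}).
#'
#' @param path YAML file, or \code{NULL} for pure defaults.
#' @param overrides Character vector of \code{key=value} overrides.
#' @return An \code{ale_config}.
#' @export
read_config <- function(path = NULL, overrides = character()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad override (expected key=value): ", ov)
    vals[[kv[1]]] <- utils::type.convert(kv[2], as.is = TRUE)
  }
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical YAML serialization; embedded in every output header
#' so outputs from different configurations are detectable.
#'
#' @param cfg An \code{ale_config}.
#' @return 32-character hex string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full joint ALE analysis
#'
#' For each requested effect direction, independently: normalize foci to
#' Talairach, build per-study likelihood maps (8 mm FWHM Gaussian, union
#' combination), average within condition, sum the two condition means into
#' the joint map, sample the permutation null, convert to voxelwise
#' p-values, threshold at FDR q, extract clusters (volume floor, minimum
#' study support), and attribute each cluster to the conditions by the
#' intensity-ratio contribution statistic.
#'
#' A direction with no foci, or with foci from only one condition, yields a
#' valid empty result with an explanatory log line.
#'
#' @param foci An \code{ale_foci} data frame or a path to a foci table.
#' @param cfg An \code{ale_config}.
#' @param mask Logical 3D array on the analysis grid, a NIfTI path, or
#'   \code{NULL} for the built-in ellipsoid mask.
#' @param out_dir If non-NULL, writes per-direction NIfTI maps (joint,
#'   p-value, cluster labels), the cluster table TSV, and a JSON run
#'   manifest there.
#' @param dry_run Validate inputs, compute counts and write the manifest,
#'   but skip map building and inference.
#' @return A list of class \code{ale_result}: one entry per direction
#'   (each with \code{joint}, \code{pvalues}, \code{supra}, \code{clusters},
#'   \code{table}, \code{means}, \code{null}), plus \code{manifest},
#'   \code{log}, \code{grid}, \code{config}.
#' @export
run_analysis <- function(foci, cfg = analysis_config(), mask = NULL,
                         out_dir = NULL, dry_run = FALSE) {
  log_lines <- character()
  say <- function(fmt, ...) {
    log_lines[length(log_lines) + 1] <<- sprintf(fmt, ...)
    invisible(NULL)
  }
  if (is.character(foci)) foci <- parse_foci_table(foci)
  n_read <- nrow(foci)
  foci <- normalize_space(foci, cfg$lancaster_variant)
  conditions <- cfg$conditions
  if (is.null(conditions)) conditions <- sort(unique(foci$condition))
  stopifnot(length(conditions) == 2)
  grid <- ale_grid(cfg$voxel_mm, cfg$xlim, cfg$ylim, cfg$zlim)
  kernel <- kernel_spec(cfg$fwhm_mm, cfg$trunc_sd)
  if (is.null(mask)) mask <- ellipsoid_mask(grid)
  else if (is.character(mask)) mask <- read_mask(mask, grid)
  stopifnot(identical(as.integer(dim(mask)), grid$dim))

  hash <- config_hash(cfg)
  say("config hash %s, seed %d", hash, cfg$seed)
  say("foci read: %d", n_read)
  counts <- table(foci$condition)
  nstud <- tapply(foci$study_id, foci$condition,
                  function(s) length(unique(s)))
  for (cd in conditions)
    say("condition %s: %d foci across %d studies", cd,
        if (cd %in% names(counts)) counts[[cd]] else 0L,
        if (cd %in% names(nstud)) nstud[[cd]] else 0L)

  manifest <- list(seed = cfg$seed, config_hash = hash,
                   config = unclass(cfg),
                   conditions = conditions,
                   n_foci = n_read,
                   n_foci_per_condition = as.list(counts),
                   n_studies_per_condition = as.list(nstud))

  results <- list()
  if (!dry_run) {
    for (dname in cfg$directions) {
      sub <- foci[foci$direction == dname, , drop = FALSE]
      say("direction %s: %d foci", dname, nrow(sub))
      present <- conditions %in% unique(sub$condition)
      if (nrow(sub) == 0 || !all(present)) {
        say("direction %s: skipped (missing foci for condition(s): %s); empty result",
            dname, paste(conditions[!present], collapse = ", "))
        results[[dname]] <- .empty_direction_result(conditions)
        next
      }
      dseed <- cfg$seed + match(dname, .DIRECTIONS) - 1L
      means <- condition_maps(sub, grid, kernel, mask, conditions)
      joint <- joint_map(means[[1]], means[[2]])
      null <- permutation_null(sub, grid, kernel, mask,
                               n_permutations = cfg$n_permutations,
                               seed = dseed, conditions = conditions)
      pvals <- voxel_pvalues(joint, null, mask)
      supra <- fdr_threshold(pvals, cfg$fdr_q, mask)
      clusters <- extract_clusters(supra, grid, joint, sub, kernel,
                                   connectivity = cfg$connectivity,
                                   min_volume_mm3 = cfg$min_cluster_volume_mm3,
                                   min_study_support = cfg$min_study_support)
      tab <- contribution_table(clusters, means,
                                method = cfg$contribution_method,
                                grid = grid, band = cfg$shared_band)
      say("direction %s: %d suprathreshold voxels, %d retained clusters",
          dname, sum(supra), nrow(tab))
      results[[dname]] <- list(joint = joint, pvalues = pvals, supra = supra,
                               clusters = clusters, table = tab,
                               means = means, null = null, seed = dseed)
    }
  }

  out <- c(results,
           list(manifest = manifest, log = log_lines, grid = grid,
                config = cfg, foci = foci))
  class(out) <- "ale_result"
  if (!is.null(out_dir)) .write_outputs(out, out_dir, mask)
  out
}

.empty_direction_result <- function(conditions) {
  list(joint = NULL, pvalues = NULL, supra = NULL, clusters = list(),
       table = contribution_table(list(),
                                  stats::setNames(list(array(0, c(1, 1, 1)),
                                                       array(0, c(1, 1, 1))),
                                                  conditions)),
       means = NULL, null = NULL, seed = NA_integer_)
}

# Writes the result bundle: per-direction NIfTI maps with the config hash in
# the descrip header field, cluster tables as commented TSV, and the JSON
# manifest + log.
.write_outputs <- function(res, out_dir, mask) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- res$manifest$config_hash
  stamp_write <- function(values, path) {
    img <- RNifti::asNifti(array(as.numeric(values), dim = res$grid$dim))
    RNifti::qform(img) <- structure(res$grid$affine, code = 2L)
    RNifti::sform(img) <- structure(res$grid$affine, code = 2L)
    img$descrip <- paste0("jointALE cfg:", substr(hash, 1, 12))
    RNifti::writeNifti(img, path)
  }
  for (dname in res$config$directions) {
    r <- res[[dname]]
    if (is.null(r)) next
    tag <- tolower(dname)
    if (!is.null(r$joint)) {
      stamp_write(r$joint, file.path(out_dir, paste0("joint_", tag, ".nii.gz")))
      stamp_write(r$pvalues, file.path(out_dir, paste0("pvalues_", tag, ".nii.gz")))
      stamp_write(attr(r$clusters, "label_map"),
                  file.path(out_dir, paste0("clusters_", tag, ".nii.gz")))
    }
    write_cluster_table(r$table, file.path(out_dir, paste0("clusters_", tag, ".tsv")),
                        hash = hash, seed = res$config$seed)
  }
  jsonlite::write_json(res$manifest,
                       file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(res$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Write a cluster/contribution table as TSV
#'
#' Percentages are formatted to one decimal place; coordinates and volume
#' to one decimal. Header comment lines (\code{#}) carry the config hash
#' and seed.
#'
#' @param tab A contribution table.
#' @param path Output path.
#' @param hash,seed Provenance values for the header.
#' @export
write_cluster_table <- function(tab, path, hash = NULL, seed = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(paste0("# config_hash: ", hash), con)
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  out <- tab
  for (v in grep("^(peak|center)_|^volume", names(out), value = TRUE))
    out[[v]] <- sprintf("%.1f", out[[v]])
  for (v in grep("^pct_", names(out), value = TRUE))
    out[[v]] <- sprintf("%.1f", out[[v]])
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.ale_result <- function(x, ...) {
  cat("Joint ALE analysis\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}
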