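# Shared fixture builders. Everything is generated in code; no data files.

# small grid starting at (0,0,0) mm with n voxels per axis
toy_grid <- function(n = 20, vox = 2) {
  ale_grid(vox, xlim = c(0, (n - 1) * vox), ylim = c(0, (n - 1) * vox),
           zlim = c(0, (n - 1) * vox))
}

all_mask <- function(grid) array(TRUE, dim = grid$dim)

# minimal foci data frame in the working space
make_foci <- function(xyz, study = "s1", condition = "A",
                      direction = "DEFICIT") {
  xyz <- matrix(xyz, ncol = 3)
  as_foci(data.frame(study_id = study, condition = condition,
                     space = "TAL_NATIVE",
                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                     direction = direction),
          single_condition = length(unique(condition)) == 1)
}

# brute-force study map: per-voxel loop over all voxels and foci, no shared
# code with study_map's cube accumulation
brute_study_map <- function(xyz, grid, kernel, mask = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  out <- array(0, dim = grid$dim)
  for (i in seq_len(grid$dim[1])) for (j in seq_len(grid$dim[2]))
    for (k in seq_len(grid$dim[3])) {
      v <- vox2mm(grid, c(i, j, k))
      q <- 1
      for (f in seq_len(nrow(xyz))) {
        d <- sqrt(sum((v - xyz[f, ])^2))
        p <- if (d >= kernel$trunc_mm) 0 else
          min(max(grid$voxel_mm^3 *
                    (2 * pi * kernel$sigma_mm^2)^(-3 / 2) *
                    exp(-d^2 / (2 * kernel$sigma_mm^2)), 0), 1)
        q <- q * (1 - p)
      }
      out[i, j, k] <- 1 - q
    }
  if (!is.null(mask)) out[!mask] <- 0
  out
}

# a synthetic 313-row corpus with the published shape: 25 studies,
# 197 foci for condition 1 and 116 for condition 2, coordinates arbitrary
corpus_shape_fixture <- function(path) {
  set.seed(42)
  per_study_a <- c(rep(15, 12), 17)        # 13 studies, 197 foci
  per_study_b <- c(rep(10, 8), rep(9, 4))  # 12 studies, 116 foci
  rows <- list()
  add <- function(cond, i, n) {
    rows[[length(rows) + 1]] <<- data.frame(
      study_id = sprintf("%s%02d", cond, i), condition = cond,
      space = "TAL_NATIVE",
      x = round(runif(n, -60, 60), 1), y = round(runif(n, -80, 60), 1),
      z = round(runif(n, -40, 60), 1), direction = "DEFICIT")
  }
  for (i in seq_along(per_study_a)) add("ASD", i, per_study_a[i])
  for (i in seq_along(per_study_b)) add("SCZ", i, per_study_b[i])
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
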