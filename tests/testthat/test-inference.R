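test_that("add-one p-values count the null tail exactly", {
  # extreme: observed beats all N null values
  nullv <- seq(0.1, 1, length.out = 10)
  expect_equal(voxel_pvalues(2, nullv), 1 / 11)
  # observed at zero is never significant
  expect_equal(voxel_pvalues(0, nullv), 1)
  # observed at the median of an odd-sized sample, counted by hand
  nullv <- c(5, 1, 4, 2, 3)
  obs <- 3
  cnt <- sum(nullv >= obs)  # 3
  expect_equal(voxel_pvalues(obs, nullv), (1 + cnt) / (1 + 5))
  # ties count as >=
  expect_equal(voxel_pvalues(5, nullv), 2 / 6)
  # monotone non-increasing in the observed value
  obs_grid <- seq(0, 6, by = 0.5)
  expect_true(all(diff(voxel_pvalues(obs_grid, nullv)) <= 0))
})

test_that("histogram null agrees with exact counting to bin resolution", {
  grid <- toy_grid(n = 10, vox = 4)
  mask <- all_mask(grid)
  k <- kernel_spec(8)
  foci <- rbind(
    make_foci(rbind(c(10, 10, 10), c(20, 20, 20)), study = "a1",
              condition = "A"),
    make_foci(rbind(c(14, 14, 14), c(30, 10, 20), c(8, 30, 12)),
              study = "b1", condition = "B"))
  foci <- as_foci(foci)
  null <- permutation_null(foci, grid, k, mask, n_permutations = 3, seed = 9)
  expect_s3_class(null, "ale_null")
  expect_equal(null$n_values, 3 * sum(mask))
  expect_equal(sum(null$counts), null$n_values)
  # bounds: pooled joint values live in [0, 2] by construction
  expect_gte(min(which(null$counts > 0)), 1)
  # determinism under the seed
  null2 <- permutation_null(foci, grid, k, mask, n_permutations = 3, seed = 9)
  expect_identical(null, null2)
  null3 <- permutation_null(foci, grid, k, mask, n_permutations = 3, seed = 10)
  expect_false(identical(null$counts, null3$counts))
  # with one study per condition the null joint maximum cannot exceed
  # twice the kernel peak union bound
  means <- condition_maps(foci, grid, k, mask)
  joint <- joint_map(means[[1]], means[[2]])
  peak_bin <- max(which(null$counts > 0))
  expect_lte(peak_bin * null$width, 2)
  p <- voxel_pvalues(joint, null, mask)
  expect_true(all(p > 0 & p <= 1))
  # a hand-built histogram null reproduces exact-vector p-values when the
  # null values are well separated relative to the bin width
  v <- c(0.125, 0.25, 0.5, 0.75, 1.0)
  nb <- 32768L
  w <- 2 / nb
  hn <- structure(list(counts = tabulate(pmin(floor(v / w) + 1, nb), nb),
                       width = w, n_bins = nb, n_values = length(v)),
                  class = "ale_null")
  for (obs in c(0.1, 0.3, 0.6, 0.75, 1.5))
    expect_equal(voxel_pvalues(obs, hn), voxel_pvalues(obs, v))
})

test_that("permutation null of single-focus studies is bounded by the kernel peak", {
  grid <- toy_grid(n = 10, vox = 4)
  mask <- all_mask(grid)
  k <- kernel_spec(8)
  foci <- as_foci(rbind(make_foci(c(10, 10, 10), study = "a1", condition = "A"),
                        make_foci(c(30, 30, 30), study = "b1", condition = "B")))
  null <- permutation_null(foci, grid, k, mask, n_permutations = 5, seed = 1)
  top <- max(which(null$counts > 0)) * null$width
  expect_lte(top, 2 * kernel_prob(0, k, grid$voxel_mm^3) + null$width)
})

test_that("BH thresholding matches the step-up rule by hand", {
  p <- array(c(0.01, 0.02, 0.04, 0.9), dim = c(4, 1, 1))
  got <- fdr_threshold(p, q = 0.05)
  # by hand: sorted p vs k*q/m = (0.0125, 0.025, 0.0375, 0.05):
  # largest k with p_(k) <= k q / m is k = 2, so exactly the two smallest pass
  expect_equal(as.vector(got), c(TRUE, TRUE, FALSE, FALSE))
  # all p = 1: nothing survives
  expect_false(any(fdr_threshold(array(1, c(3, 3, 3)), 0.05)))
  # boundary: all p = q/m survive at k = m
  m <- 27
  expect_true(all(fdr_threshold(array(0.05 / m, c(3, 3, 3)), 0.05)))
  # independent reference route on random p-values
  set.seed(8)
  pr <- array(runif(64)^2, dim = c(4, 4, 4))
  got <- fdr_threshold(pr, 0.1)
  ps <- sort(as.vector(pr))
  ks <- which(ps <= seq_along(ps) * 0.1 / 64)
  want <- if (length(ks) == 0) array(FALSE, c(4, 4, 4)) else
    pr <= ps[max(ks)]
  expect_equal(got, want)
})

test_that("seeded analyses are bit-reproducible", {
  grid <- toy_grid(n = 8, vox = 4)
  mask <- all_mask(grid)
  k <- kernel_spec(8)
  set.seed(21)
  foci <- as_foci(rbind(
    make_foci(matrix(runif(9, 4, 28), 3), study = "a1", condition = "A"),
    make_foci(matrix(runif(6, 4, 28), 2), study = "b1", condition = "B")))
  run <- function() {
    means <- condition_maps(foci, grid, k, mask)
    joint <- joint_map(means[[1]], means[[2]])
    null <- permutation_null(foci, grid, k, mask, 50, seed = 5)
    voxel_pvalues(joint, null, mask)
  }
  expect_identical(run(), run())
})
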