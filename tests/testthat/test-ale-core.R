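test_that("kernel probability matches the closed-form Gaussian density", {
  k <- kernel_spec(8)
  # sigma from FWHM
  expect_equal(k$sigma_mm, 8 / (2 * sqrt(2 * log(2))))
  expect_equal(k$sigma_mm, 3.3973, tolerance = 1e-4)
  # density x voxel volume at distance 0, computed independently via dnorm
  expect_equal(kernel_prob(0, k, 8), 8 * dnorm(0, 0, k$sigma_mm)^3)
  # isotropy: same value at distance d in any direction, and truncation
  expect_equal(kernel_prob(5, k, 8), kernel_prob(5, k, 8))
  expect_identical(kernel_prob(k$trunc_mm, k, 8), 0)
  expect_identical(kernel_prob(k$trunc_mm + 10, k, 8), 0)
  expect_gt(kernel_prob(k$trunc_mm - 1e-6, k, 8), 0)
})

test_that("kernel mass over a containing grid is about 1", {
  k <- kernel_spec(8)
  grid <- toy_grid(n = 17, vox = 2)  # 32 mm box holds the 4-sigma sphere
  ctr <- vox2mm(grid, ceiling(grid$dim / 2))
  m <- study_map(make_foci(ctr), grid, k)
  # single focus: map equals the kernel field, so its sum is the mass
  expect_equal(sum(m), 1, tolerance = 0.02)
})

test_that("study map is the union of per-focus probabilities", {
  k <- kernel_spec(8)
  grid <- toy_grid(n = 12, vox = 2)
  ctr <- vox2mm(grid, c(6, 6, 6))
  # single focus: map equals the kernel probability field
  m1 <- study_map(make_foci(ctr), grid, k)
  d <- sqrt(outer(outer((vox2mm(grid, cbind(1:12, 1, 1))[, 1] - ctr[1])^2,
                        (vox2mm(grid, cbind(1, 1:12, 1))[, 2] - ctr[2])^2, "+"),
                  (vox2mm(grid, cbind(1, 1, 1:12))[, 3] - ctr[3])^2, "+"))
  expect_equal(m1, kernel_prob(d, k, 8), tolerance = 1e-12)
  # two coincident foci: 2p - p^2
  m2 <- study_map(make_foci(rbind(ctr, ctr)), grid, k)
  expect_equal(m2, 2 * m1 - m1^2, tolerance = 1e-12)
  # empty study errors
  expect_error(study_map(make_foci(ctr)[0, ], grid, k), "no foci")
})

test_that("study map matches the brute-force union oracle", {
  k <- kernel_spec(8)
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(3:5, 1)
    grid <- toy_grid(n = sample(10:12, 1), vox = 2)
    xyz <- matrix(runif(3 * n, 2, max(grid$dim) * 2 - 2), ncol = 3)
    mask <- all_mask(grid)
    mask[1, , ] <- FALSE  # exercise masking too
    got <- study_map(make_foci(xyz), grid, k, mask)
    want <- brute_study_map(xyz, grid, k, mask)
    expect_lt(max(abs(got - want)), 1e-12)
  }
})

test_that("adding a focus never decreases the study map", {
  k <- kernel_spec(8)
  grid <- toy_grid(n = 14, vox = 2)
  set.seed(3)
  xyz <- matrix(runif(9, 4, 24), ncol = 3)
  m_all <- study_map(make_foci(xyz), grid, k)
  m_two <- study_map(make_foci(xyz[1:2, ]), grid, k)
  expect_true(all(m_all >= m_two - 1e-15))
  expect_true(all(m_all >= 0 & m_all <= 1))
})

test_that("condition mean and joint maps are elementwise arithmetic", {
  grid <- toy_grid(n = 6)
  set.seed(4)
  maps <- replicate(3, array(runif(prod(grid$dim)), dim = grid$dim),
                    simplify = FALSE)
  mn <- condition_mean_map(maps)
  expect_equal(mn, (maps[[1]] + maps[[2]] + maps[[3]]) / 3)
  expect_equal(condition_mean_map(maps[c(1, 1, 1)]), maps[[1]])
  zero <- array(0, dim = grid$dim)
  expect_equal(condition_mean_map(list(maps[[1]], zero)), maps[[1]] / 2)
  # joint: sum, commutative, additive identity
  expect_equal(joint_map(mn, zero), mn)
  expect_equal(joint_map(mn, maps[[2]]), joint_map(maps[[2]], mn))
  expect_equal(joint_map(mn, maps[[2]]), mn + maps[[2]])
  expect_error(condition_mean_map(list(maps[[1]], array(0, c(2, 2, 2)))),
               "different grids")
  expect_error(joint_map(mn, array(0, c(2, 2, 2))), "different grids")
})

test_that("grid index/mm round-trips are exact", {
  grid <- ale_grid(2)
  expect_equal(grid$dim, c(71L, 87L, 65L))
  set.seed(5)
  ijk <- cbind(sample(71, 50, TRUE), sample(87, 50, TRUE), sample(65, 50, TRUE))
  expect_equal(mm2vox(grid, vox2mm(grid, ijk)), ijk)
  expect_true(all(diff(range(vox2mm(grid, ijk))) >= 0))
  # box spans >= 100 mm per axis at defaults
  expect_true(all((grid$dim - 1) * grid$voxel_mm >= 100))
})
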