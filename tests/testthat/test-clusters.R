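# brute-force reference labelling: propagate labels until fixed point,
# adjacency decided by pairwise Chebyshev/Manhattan distance checks
brute_label <- function(supra, connectivity) {
  idx <- which(supra, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(integer(0))
  lab <- seq_len(n)
  adj <- function(a, b) {
    d <- abs(idx[a, ] - idx[b, ])
    if (max(d) > 1) return(FALSE)
    s <- sum(d)
    switch(as.character(connectivity),
           "6" = s == 1, "18" = s >= 1 && s <= 2, "26" = s >= 1)
  }
  repeat {
    changed <- FALSE
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a != b && adj(a, b) && lab[b] > lab[a]) {
        lab[lab == lab[b]] <- lab[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

# partition signature independent of label numbering
partition_of <- function(lab) unname(sort(table(lab)))

test_that("connectivity rules distinguish face, edge and corner adjacency", {
  supra <- array(FALSE, c(5, 5, 5))
  supra[2, 2, 2] <- TRUE; supra[3, 2, 2] <- TRUE  # face-adjacent pair
  expect_equal(max(jointALE:::.label_components(supra, 6)), 1)
  expect_equal(max(jointALE:::.label_components(supra, 26)), 1)
  supra <- array(FALSE, c(5, 5, 5))
  supra[2, 2, 2] <- TRUE; supra[3, 3, 3] <- TRUE  # corner-diagonal pair
  expect_equal(max(jointALE:::.label_components(supra, 26)), 1)
  expect_equal(max(jointALE:::.label_components(supra, 18)), 2)
  expect_equal(max(jointALE:::.label_components(supra, 6)), 2)
  supra <- array(FALSE, c(5, 5, 5))
  supra[2, 2, 2] <- TRUE; supra[2, 3, 3] <- TRUE  # edge-diagonal pair
  expect_equal(max(jointALE:::.label_components(supra, 18)), 1)
  expect_equal(max(jointALE:::.label_components(supra, 6)), 2)
})

test_that("component labelling agrees with the brute-force oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    supra <- array(runif(16^3) < 0.08, dim = c(16, 16, 16))
    for (conn in c(6, 18, 26)) {
      lab <- jointALE:::.label_components(supra, conn)
      got <- partition_of(lab[lab > 0])
      want <- partition_of(brute_label(supra, conn))
      expect_equal(got, want, info = sprintf("seed %d conn %d", seed, conn))
    }
  }
})

test_that("volume and study-support filters follow the strict thresholds", {
  grid <- toy_grid(n = 16, vox = 2)  # voxel = 8 mm^3
  k <- kernel_spec(8)
  joint <- array(1, dim = grid$dim)
  supra <- array(FALSE, grid$dim)
  supra[2:13, 2, 2] <- TRUE           # 12 voxels = 96 mm^3: dropped (<= 100)
  supra[2:14, 6, 6] <- TRUE           # 13 voxels = 104 mm^3: retained
  # two studies with foci near the retained run of voxels
  foci <- as_foci(rbind(
    make_foci(c(12, 10, 10), study = "a1", condition = "A"),
    make_foci(c(16, 10, 10), study = "b1", condition = "B")))
  cl <- extract_clusters(supra, grid, joint, foci, k,
                         min_volume_mm3 = 100, min_study_support = 2)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$volume_mm3, 104)
  expect_setequal(cl[[1]]$support$study_id, c("a1", "b1"))
  # label map matches retained clusters
  expect_equal(max(attr(cl, "label_map")), 1)
  expect_equal(sum(attr(cl, "label_map") == 1), 13)
  # single-study clusters are not reported
  cl1 <- extract_clusters(supra, grid, joint, foci[1, ], k,
                          min_volume_mm3 = 100, min_study_support = 2)
  expect_length(cl1, 0)
  # support radius is the kernel truncation radius: a far focus cannot
  # support the cluster
  far <- as_foci(rbind(make_foci(c(12, 10, 10), study = "a1", condition = "A"),
                       make_foci(c(12, 10 + k$trunc_mm + 8, 10),
                                 study = "b1", condition = "B")))
  clf <- extract_clusters(supra, grid, joint, far, k,
                          min_volume_mm3 = 100, min_study_support = 2)
  expect_length(clf, 0)
})

test_that("clusters are sorted by volume and carry peak and center of mass", {
  grid <- toy_grid(n = 16, vox = 2)
  k <- kernel_spec(8)
  joint <- array(0, dim = grid$dim)
  supra <- array(FALSE, grid$dim)
  supra[2:14, 2, 2] <- TRUE
  supra[2:15, 8:9, 8:9] <- TRUE       # larger block
  joint[supra] <- 1
  joint[10, 8, 8] <- 5                # peak inside the big block
  foci <- as_foci(rbind(
    make_foci(rbind(c(10, 4, 4), c(18, 16, 16)), study = "a1", condition = "A"),
    make_foci(rbind(c(14, 4, 4), c(20, 16, 16)), study = "b1", condition = "B")))
  cl <- extract_clusters(supra, grid, joint, foci, k)
  expect_equal(vapply(cl, `[[`, numeric(1), "volume_mm3"),
               sort(vapply(cl, `[[`, numeric(1), "volume_mm3"),
                    decreasing = TRUE))
  expect_equal(cl[[1]]$peak_mm, vox2mm(grid, c(10, 8, 8)))
  com <- cl[[1]]$center_mm
  expect_true(all(com >= vox2mm(grid, c(2, 8, 8)) - 1e-9) &&
                all(com <= vox2mm(grid, c(15, 9, 9)) + 1e-9))
})
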