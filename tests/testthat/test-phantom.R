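smallSpec <- function(seed = 3L, effect = 2, n = 4L, fwhm = 2,
                      blobs = data.frame(ci = 6, cj = 6, ck = 6,
                                         radius = 2, effect = effect)) {
  phantomSpec(grid_shape = c(12L, 12L, 12L), n_per_group = n,
              blobs = blobs, smooth_fwhm = fwhm, seed = seed)
}

test_that("phantom generation is bit-reproducible given the seed", {
  d1 <- file.path(tempdir(), "ph-rep1"); d2 <- file.path(tempdir(), "ph-rep2")
  p1 <- generatePhantomCohort(smallSpec(), d1)
  p2 <- generatePhantomCohort(smallSpec(), d2)
  for (s in seq_len(nrow(p1$manifest))) {
    a <- loadVolume(p1$manifest$gm_path[s])@data
    b <- loadVolume(p2$manifest$gm_path[s])@data
    expect_identical(a, b)
  }
  p3 <- generatePhantomCohort(smallSpec(seed = 4L),
                              file.path(tempdir(), "ph-rep3"))
  expect_false(identical(loadVolume(p3$manifest$gm_path[1])@data,
                         loadVolume(p1$manifest$gm_path[1])@data))
})

test_that("patient densities drop by effect * noise_sd inside blobs", {
  # no smoothing, so the injected shift is measured unattenuated
  ph <- generatePhantomCohort(smallSpec(seed = 21L, n = 30L, fwhm = 0),
                              file.path(tempdir(), "ph-shift"))
  lab <- ph$manifest$label
  vols <- lapply(ph$manifest$gm_path, function(p) loadVolume(p)@data)
  mu_hc <- Reduce(`+`, vols[lab == 0]) / sum(lab == 0)
  mu_scz <- Reduce(`+`, vols[lab == 1]) / sum(lab == 1)
  diff <- (mu_scz - mu_hc)[discriminativeMask(ph$ground_truth)]
  # nominal shift is -effect * noise_sd = -0.2
  expect_equal(mean(diff), -0.2, tolerance = 0.1)
  expect_gte(mean(diff < 0), 0.95)
})

test_that("null phantoms (no or zero-effect blobs) show no group difference", {
  noblob <- phantomSpec(grid_shape = c(12L, 12L, 12L), n_per_group = 10L,
                        blobs = data.frame(ci = numeric(), cj = numeric(),
                                           ck = numeric(),
                                           radius = numeric(),
                                           effect = numeric()),
                        seed = 5L)
  ph <- generatePhantomCohort(noblob, file.path(tempdir(), "ph-null"))
  expect_identical(sum(discriminativeMask(ph$ground_truth)), 0L)
  lab <- ph$manifest$label
  means <- vapply(ph$manifest$gm_path,
                  function(p) mean(loadVolume(p)@data), numeric(1))
  t <- t.test(means[lab == 1], means[lab == 0])$statistic
  expect_lt(abs(t), 4)

  ph0 <- generatePhantomCohort(smallSpec(seed = 5L, effect = 0, n = 10L),
                               file.path(tempdir(), "ph-eff0"))
  lab0 <- ph0$manifest$label
  vols <- lapply(ph0$manifest$gm_path, function(p) loadVolume(p)@data)
  mu_d <- Reduce(`+`, vols[lab0 == 1]) / 10 - Reduce(`+`, vols[lab0 == 0]) / 10
  inblob <- mu_d[discriminativeMask(ph0$ground_truth)]
  expect_lt(abs(mean(inblob)), 0.05)  # sampling noise only
})

test_that("group separation inside blobs grows with effect size", {
  gaps <- vapply(c(0.5, 1.5, 3), function(eff) {
    gap <- 0
    for (seed in c(31L, 32L, 33L)) {
      ph <- generatePhantomCohort(smallSpec(seed = seed, effect = eff,
                                            n = 8L),
                                  file.path(tempdir(),
                                            sprintf("ph-mono-%d-%g",
                                                    seed, eff)))
      lab <- ph$manifest$label
      vols <- lapply(ph$manifest$gm_path, function(p) loadVolume(p)@data)
      mu_d <- Reduce(`+`, vols[lab == 0]) / 8 -
        Reduce(`+`, vols[lab == 1]) / 8
      gap <- gap + mean(mu_d[discriminativeMask(ph$ground_truth)])
    }
    gap / 3
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("blobs must fit the grid and groups must have >= 2 subjects", {
  expect_error(phantomSpec(grid_shape = c(12L, 12L, 12L),
                           blobs = data.frame(ci = 11, cj = 6, ck = 6,
                                              radius = 3, effect = 1)),
               "inside the grid")
  expect_error(phantomSpec(n_per_group = 1L), "2 subjects")
})

test_that("groundTruthColumns maps blob voxels to matrix columns", {
  d <- c(8L, 8L, 8L)
  blob <- data.frame(ci = 4, cj = 4, ck = 4, radius = 1.5, effect = 1)
  gt_arr <- array(FALSE, d)
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    if ((i - 4)^2 + (j - 4)^2 + (k - 4)^2 <= 1.5^2)
      gt_arr[i, j, k] <- TRUE
  gt <- new("GroundTruth", mask = gt_arr,
            effect = array(as.numeric(gt_arr), d), blobs = blob)

  # mask covering the whole grid: all blob cells come back, in column order
  full <- new("VoxelMask", mask = array(TRUE, d), affine = diag(4))
  cols <- groundTruthColumns(gt, full)
  expect_identical(cols, which(gt_arr))
  expect_identical(length(cols), 19L)  # offsets with squared norm <= 2.25

  # mask covering half the grid: only the intersecting cells
  half_arr <- array(FALSE, d); half_arr[1:4, , ] <- TRUE
  half <- new("VoxelMask", mask = half_arr, affine = diag(4))
  cols_half <- groundTruthColumns(gt, half)
  # enumerate the intersection independently
  expected <- which(gt_arr[half_arr])
  expect_identical(cols_half, expected)
  expect_identical(length(cols_half), 14L)  # blob cells with i <= 4

  # empty ground truth -> empty set
  gt0 <- new("GroundTruth", mask = array(FALSE, d),
             effect = array(0, d), blobs = blob[0, ])
  expect_identical(length(groundTruthColumns(gt0, full)), 0L)

  bad <- new("VoxelMask", mask = array(TRUE, c(6L, 6L, 6L)),
             affine = diag(4))
  expect_error(groundTruthColumns(gt, bad), "grid mismatch")
})

test_that("generated cohorts stay in [0, 1] and honor the manifest contract", {
  ph <- generatePhantomCohort(smallSpec(seed = 8L),
                              file.path(tempdir(), "ph-range"))
  expect_identical(nrow(ph$manifest), 8L)
  expect_identical(ph$manifest$label, rep(c(0L, 1L), each = 4))
  for (p in ph$manifest$gm_path) {
    v <- loadVolume(p)@data
    expect_true(all(v >= 0 & v <= 1))
  }
  # the manifest on disk is readable by the io layer
  back <- readManifest(file.path(tempdir(), "ph-range", "manifest.csv"))
  expect_identical(back$subject_id, ph$manifest$subject_id)
})
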