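# Shared fixtures, generated once per test run and memoized. The main
# fixture is the reference phantom cohort (24^3 grid, one radius-3 blob
# of effect 2.0, 30 subjects per group, seed 7) that several modules and
# the acceptance checks all exercise.

.fixture_env <- new.env(parent = emptyenv())

fixtureMemo <- function(name, make) {
  if (!exists(name, envir = .fixture_env))
    assign(name, make(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

referencePhantomSpec <- function(seed = 7L, baseline_mean = 0.5) {
  phantomSpec(grid_shape = c(24L, 24L, 24L), n_per_group = 30L,
              blobs = data.frame(ci = 12, cj = 12, ck = 12, radius = 3,
                                 effect = 2),
              baseline_mean = baseline_mean, noise_sd = 0.1,
              smooth_fwhm = 2.0, seed = seed)
}

# Phantom cohort stacked end-to-end: manifest, ground truth, training
# mask (built on the training split only), train/test cohorts, MI
# scores, top-200 features and a trained model.
phantomFixture <- function() {
  fixtureMemo("phantom", function() {
    dir <- file.path(tempdir(), "vbmednn-fixture")
    ph <- generatePhantomCohort(referencePhantomSpec(), dir)
    split <- splitCohort(ph$manifest, 0.875, seed = 11L)
    trainrows <- ph$manifest[ph$manifest$subject_id %in% split@train_ids, ]
    mask <- buildMask(lapply(trainrows$gm_path, loadVolume),
                      min_mean = 0.1, min_variance = 1e-6)
    train <- stackCohort(ph$manifest, "GM", mask,
                         subset = split@train_ids)
    test <- stackCohort(ph$manifest, "GM", mask,
                        subset = split@test_ids)
    scores <- miScores(train, n_bins = 4L)
    feats <- rankAndSelect(scores, 200L)
    model <- trainEDNN(train, feats, ednnConfig(seed = 5L))
    list(dir = dir, manifest = ph$manifest, gt = ph$ground_truth,
         split = split, mask = mask, train = train, test = test,
         scores = scores, feats = feats, model = model)
  })
}

# A small set of noisy volumes on a common grid for I/O tests.
makeVolumes <- function(n, d = c(6L, 6L, 6L), seed = 42L,
                        affine = diag(c(2, 2, 2, 1))) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    VolumeImage(array(runif(prod(d)), d), affine))
}

# Write a tiny two-subject-per-class manifest whose volumes hold the
# given voxel values; returns the manifest data.frame.
writeToyCohort <- function(values_by_subject, labels, dir,
                           d = c(4L, 4L, 4L)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(values_by_subject)
  paths <- character(n)
  for (s in seq_len(n)) {
    paths[s] <- file.path(dir, sprintf("toy%02d.nii.gz", s))
    saveVolume(VolumeImage(array(values_by_subject[[s]], d)), paths[s])
  }
  data.frame(subject_id = sprintf("t%02d", seq_len(n)),
             gm_path = paths, wm_path = paths,
             label = labels, cohort = "toy", stringsAsFactors = FALSE)
}
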