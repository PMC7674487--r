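test_that("confusion metrics follow their defining ratios", {
  m <- confusionMetrics(3, 1, 2, 2)
  expect_equal(m$accuracy, 0.625)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 0.5)
  expect_equal(m$nnp, 4)  # 1 / (0.75 + 0.5 - 1)

  perfect <- confusionMetrics(5, 0, 5, 0)
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity",
                                   "specificity", "ppv", "npv")]) == 1))
  expect_equal(perfect$nnp, 1)

  # undefined denominators become NA, not errors
  nopos <- confusionMetrics(0, 0, 4, 2)
  expect_true(is.na(nopos$ppv))
  expect_true(is.na(nopos$nnp))
  # uninformative classifier: PPV + NPV <= 1 -> NNP undefined
  expect_true(is.na(nnp(0.5, 0.5)))
  expect_error(confusionMetrics(0, 0, 0, 0), "zero")
  expect_error(confusionMetrics(-1, 0, 1, 0), "non-negative")
})

test_that("metric identities hold on random confusion tables", {
  set.seed(701)
  for (rep in 1:25) {
    cts <- as.list(sample(0:20, 4, replace = TRUE))
    names(cts) <- c("TP", "FP", "TN", "FN")
    n <- sum(unlist(cts))
    if (n == 0) next
    m <- do.call(confusionMetrics, cts)
    expect_equal(m$accuracy, (cts$TP + cts$TN) / n)
    if (!is.na(m$sensitivity))
      expect_equal(m$sensitivity, cts$TP / (cts$TP + cts$FN))
    if (!is.na(m$nnp)) {
      expect_gte(m$nnp, 1 - 1e-12)  # NNP >= 1 whenever defined
      expect_equal(m$nnp, 1 / (m$ppv + m$npv - 1))
    }
  }
})

test_that("stratified splits are deterministic, disjoint and balanced", {
  man <- data.frame(subject_id = sprintf("s%03d", 1:40),
                    label = rep(c(0L, 1L), each = 20))
  s1 <- splitCohort(man, 0.75, seed = 5L)
  s2 <- splitCohort(man, 0.75, seed = 5L)
  expect_identical(s1@train_ids, s2@train_ids)
  expect_identical(sort(c(s1@train_ids, s1@test_ids)), sort(man$subject_id))
  expect_length(s1@train_ids, 30)

  s3 <- splitCohort(man, 0.75, seed = 6L)
  expect_false(identical(sort(s1@train_ids), sort(s3@train_ids)))

  # class ratio within one subject of the stratified target
  set.seed(702)
  for (rep in 1:15) {
    n0 <- sample(5:60, 1); n1 <- sample(5:60, 1)
    fr <- runif(1, 0.3, 0.9)
    mm <- data.frame(subject_id = sprintf("r%03d", seq_len(n0 + n1)),
                     label = c(rep(0L, n0), rep(1L, n1)))
    sp <- splitCohort(mm, fr, seed = rep)
    lab <- mm$label[match(sp@train_ids, mm$subject_id)]
    expect_lte(abs(sum(lab == 0) - n0 * fr), 1)
    expect_lte(abs(sum(lab == 1) - n1 * fr), 1)
  }

  expect_error(splitCohort(data.frame(subject_id = c("a", "b"),
                                      label = c(0L, 0L)), 0.5),
               "both classes")
})

test_that("ROC sweep matches the pairwise-concordance oracle and pROC", {
  r <- rocAuc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[1], 0)

  r2 <- rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r2$auc, 0.75)

  set.seed(703)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    # coarse scores force ties across and within classes
    sc <- round(runif(n), 1)
    lb <- sample(0:1, n, replace = TRUE)
    if (length(unique(lb)) < 2) lb[1] <- 1 - lb[1]
    expect_equal(rocAuc(sc, lb)$auc, bruteAUC(sc, lb), tolerance = 1e-12)
  }

  if (requireNamespace("pROC", quietly = TRUE)) {
    sc <- c(0.12, 0.8, 0.5, 0.5, 0.33, 0.9, 0.41, 0.6)
    lb <- c(0, 1, 0, 1, 0, 1, 1, 0)
    ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE)))
    expect_equal(rocAuc(sc, lb)$auc, ref, tolerance = 1e-12)
  }

  # label-independent scores: AUC near 1/2
  set.seed(704)
  sc <- runif(2000); lb <- sample(0:1, 2000, replace = TRUE)
  expect_equal(rocAuc(sc, lb)$auc, 0.5, tolerance = 0.05)
  expect_error(rocAuc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("bootstrap intervals are seeded, bracketing and tight when degenerate", {
  acc <- function(l, s) mean(as.integer(s >= 0.5) == l)
  y <- rep(c(0L, 1L), each = 10)
  perfect <- c(rep(0.1, 10), rep(0.9, 10))
  ci <- bootstrapCi(y, perfect, acc, n_boot = 200L, seed = 3L)
  expect_equal(as.numeric(ci), c(1, 1))

  set.seed(705)
  noisy <- ifelse(runif(20) < 0.8, y, 1 - y) * 0.8 + 0.1
  ci2 <- bootstrapCi(y, noisy, acc, n_boot = 500L, seed = 3L)
  est <- acc(y, noisy)
  expect_lte(ci2[1], est); expect_gte(ci2[2], est)
  ci3 <- bootstrapCi(y, noisy, acc, n_boot = 500L, seed = 3L)
  expect_identical(as.numeric(ci2), as.numeric(ci3))

  # metrics needing both classes trigger redraws on tiny samples
  sens <- function(l, s) sum(s >= 0.5 & l == 1) / sum(l == 1)
  ci4 <- bootstrapCi(c(0L, 1L, 1L), c(0.2, 0.9, 0.8), sens,
                     n_boot = 100L, seed = 9L,
                     need_both_classes = TRUE)
  expect_gte(attr(ci4, "n_redrawn"), 0L)
  expect_error(bootstrapCi(1:3, 1:3, acc, n_boot = 10L), "n_boot")
})

test_that("model evaluation assembles a consistent report", {
  fx <- phantomFixture()
  rep <- evaluateModel(fx$model, fx$test, n_boot = 200L, seed = 2L,
                       cohort_tag = "phantom")
  expect_s4_class(rep, "EvalReport")
  expect_equal(sum(rep@counts), length(subjectIds(fx$test)))
  m <- reportMetrics(rep)
  expect_true(all(unlist(m[c("accuracy", "sensitivity", "specificity")])
                  >= 0))
  expect_gte(rep@auc, 0.5)
  # CI brackets the point estimate
  expect_lte(rep@ci$accuracy[1], m$accuracy)
  expect_gte(rep@ci$accuracy[2], m$accuracy)

  f <- withr::local_tempfile(fileext = ".json")
  writeEvalReport(rep, f)
  f2 <- withr::local_tempfile(fileext = ".json")
  writeEvalReport(rep, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("zero-epoch transfer reduces to frozen evaluation", {
  fx <- phantomFixture()
  man8 <- fx$manifest[fx$manifest$subject_id %in% subjectIds(fx$test), ]
  split2 <- splitCohort(man8, 0.5, seed = 31L)
  cfg0 <- fx$model@config; cfg0$max_epochs <- 0L
  tr <- transferRetrain(fx$model, fx$test, split2, cfg0,
                        n_boot = 150L, seed = 4L)
  direct <- evaluateModel(fx$model, fx$test, subset = split2@test_ids,
                          n_boot = 150L, seed = 4L)
  expect_identical(tr$retrained@counts, direct@counts)
  expect_equal(reportMetrics(tr$retrained), reportMetrics(direct))
  expect_identical(tr$model@W1, fx$model@W1)
})

test_that("retraining on an identically distributed cohort changes little", {
  fx <- phantomFixture()
  accs <- c()
  for (seed in c(81L, 82L)) {
    ph2 <- generatePhantomCohort(referencePhantomSpec(seed = seed),
                                 file.path(tempdir(),
                                           sprintf("nodrift-%d", seed)))
    co <- stackCohort(ph2$manifest, "GM", fx$mask)
    sp <- splitCohort(ph2$manifest, 92 / 132, seed = seed)
    cfg <- ednnConfig(seed = 5L, max_epochs = 150L)
    tr <- transferRetrain(fx$model, co, sp, cfg, n_boot = 150L,
                          seed = seed)
    accs <- rbind(accs, c(reportMetrics(tr$unseen)$accuracy,
                          reportMetrics(tr$retrained)$accuracy))
  }
  gap <- abs(mean(accs[, 1]) - mean(accs[, 2]))
  expect_lt(gap, 0.10)
})
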