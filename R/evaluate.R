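#' Stratified train/test split of a cohort manifest
#'
#' Partitions subjects into train and test sets stratified by diagnosis.
#' The total training count is `round(n * train_fraction)`; per-class
#' counts are allocated by largest-remainder rounding, so class
#' proportions in both halves are within one subject of the stratified
#' target. With 400 subjects (200/200) at fraction 0.875 this gives
#' exactly 350/50; with 132 subjects (88/44) at fraction 92/132, exactly
#' 92/40. Deterministic given the seed.
#'
#' @param manifest manifest data.frame with `subject_id` and `label`.
#' @param train_fraction fraction of subjects to train on, in (0, 1).
#' @param seed RNG seed.
#' @return a [SplitPlan].
#' @export
splitCohort <- function(manifest, train_fraction, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  y <- manifest$label
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    stop("both classes must be present to stratify", call. = FALSE)
  n_c <- vapply(classes, function(cl) sum(y == cl), integer(1))
  if (any(n_c < 2L))
    stop("a class is too small to stratify", call. = FALSE)
  total <- round(sum(n_c) * train_fraction)
  target <- n_c * train_fraction
  base <- floor(target)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(-(target - base), seq_along(classes))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  if (any(base < 1) || any(base >= n_c))
    stop("a class is too small to stratify at this fraction",
         call. = FALSE)
  train_ids <- withSeed(seed, {
    unlist(lapply(seq_along(classes), function(ci) {
      ids <- manifest$subject_id[y == classes[ci]]
      sample(ids, base[ci])
    }))
  })
  test_ids <- setdiff(manifest$subject_id, train_ids)
  new("SplitPlan", train_ids = as.character(train_ids),
      test_ids = as.character(test_ids), fraction = train_fraction,
      seed = as.integer(seed))
}

#' Number needed to predict from the predictive values
#'
#' `NNP = 1 / (PPV + NPV - 1)`, the reciprocal of the predictive summary
#' index. Smaller is better; 1 for a perfect classifier. Undefined (NA)
#' when `PPV + NPV <= 1` (the classifier adds no predictive information).
#'
#' @param ppv,npv positive/negative predictive values as proportions.
#' @return NNP, or NA when undefined.
#' @export
#' @examples
#' nnp(0.8667, 0.8333)  # 1.4286
nnp <- function(ppv, npv) {
  psi <- ppv + npv - 1
  ifelse(is.na(psi) | psi <= 0, NA_real_, 1 / psi)
}

#' The six diagnostic quantities from a confusion matrix
#'
#' Accuracy, sensitivity (TP/(TP+FN)), specificity (TN/(TN+FP)),
#' PPV (TP/(TP+FP)), NPV (TN/(TN+FN)) and NNP. A quantity whose
#' denominator is zero is NA rather than an error, as is NNP when
#' PPV + NPV <= 1.
#'
#' @param TP,FP,TN,FN non-negative confusion counts (positives are
#'   patients).
#' @return named list of the six quantities.
#' @export
#' @examples
#' confusionMetrics(3, 1, 2, 2)  # accuracy 0.625, NNP 4
confusionMetrics <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- sum(counts)
  if (n == 0) stop("all confusion counts are zero", call. = FALSE)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  ppv <- rate(TP, TP + FP); npv <- rate(TN, TN + FN)
  list(accuracy = (TP + TN) / n,
       sensitivity = rate(TP, TP + FN),
       specificity = rate(TN, TN + FP),
       ppv = ppv, npv = npv, nnp = nnp(ppv, npv))
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps the decision threshold over the unique scores (subjects tied
#' at a threshold enter together), collecting (FPR, TPR) points anchored
#' at (0,0) and (1,1), and integrates by the trapezoid rule — which
#' equals the pairwise concordance probability with ties counted 1/2.
#'
#' @param scores per-subject probabilities (higher = more patient-like).
#' @param labels binary labels, both classes present.
#' @return list with `roc` (data.frame threshold/fpr/tpr) and `auc`.
#' @export
rocAuc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("both classes must be present for ROC analysis", call. = FALSE)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / np,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / nn,
                numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] < 1 || roc$tpr[nrow(roc)] < 1)
    roc <- rbind(roc, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  list(roc = roc, auc = auc)
}

#' Percentile bootstrap confidence interval for a test-set metric
#'
#' Resamples subjects with replacement `n_boot` times and returns the
#' 2.5/97.5 percentile bounds of the metric. Resamples that collapse to
#' a single class (where the metric is undefined) are redrawn; the
#' number of redraws is attached as an attribute.
#'
#' @param labels,scores per-subject truth and predicted
#'   probability/label, resampled jointly.
#' @param metric function(labels, scores) -> scalar.
#' @param n_boot bootstrap replicates (>= 100).
#' @param seed RNG seed.
#' @param need_both_classes redraw single-class resamples.
#' @return numeric `c(lower, upper)` with attribute `n_redrawn`.
#' @export
bootstrapCi <- function(labels, scores, metric, n_boot = 2000L,
                        seed = 1L, need_both_classes = FALSE) {
  stopifnot(n_boot >= 100L, length(labels) == length(scores))
  n <- length(labels)
  withSeed(seed, {
    vals <- numeric(n_boot)
    redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        if (!need_both_classes || length(unique(labels[idx])) > 1L) break
        redrawn <- redrawn + 1L
        if (redrawn > 1000L * n_boot)
          stop("cannot draw a two-class resample", call. = FALSE)
      }
      vals[b] <- metric(labels[idx], scores[idx])
    }
    structure(stats::quantile(vals, c(0.025, 0.975), names = FALSE,
                              na.rm = TRUE),
              n_redrawn = redrawn)
  })
}

#' Evaluate a trained model on a cohort
#'
#' Predicts every subject, thresholds at 0.5 (ties toward patient),
#' and assembles the full [EvalReport]: confusion counts, the six
#' diagnostic quantities, bootstrap 95% CIs for accuracy / sensitivity /
#' specificity, ROC points and AUC.
#'
#' @param model a [TrainedEDNN].
#' @param cohort a [VbmCohort].
#' @param subset optional subject ids to evaluate on.
#' @param n_boot,seed bootstrap settings.
#' @param cohort_tag tag recorded on the report.
#' @return an [EvalReport].
#' @export
evaluateModel <- function(model, cohort, subset = NULL, n_boot = 2000L,
                          seed = 1L, cohort_tag = "cohort") {
  ids <- subjectIds(cohort)
  keep <- if (is.null(subset)) seq_along(ids) else match(subset, ids)
  if (anyNA(keep)) stop("subset ids not found in cohort", call. = FALSE)
  X <- densityMatrix(cohort)[keep, , drop = FALSE]
  y <- diagnosis(cohort)[keep]
  p <- predictProba(model, X)
  pred <- as.integer(p >= 0.5)
  TP <- sum(pred == 1 & y == 1); FP <- sum(pred == 1 & y == 0)
  TN <- sum(pred == 0 & y == 0); FN <- sum(pred == 0 & y == 1)
  metrics <- confusionMetrics(TP, FP, TN, FN)
  r <- rocAuc(p, y)
  accM <- function(l, s) mean(as.integer(s >= 0.5) == l)
  senM <- function(l, s) { pr <- as.integer(s >= 0.5)
    if (sum(l == 1) == 0) NA_real_ else sum(pr == 1 & l == 1) / sum(l == 1) }
  speM <- function(l, s) { pr <- as.integer(s >= 0.5)
    if (sum(l == 0) == 0) NA_real_ else sum(pr == 0 & l == 0) / sum(l == 0) }
  ci <- list(
    accuracy = bootstrapCi(y, p, accM, n_boot, deriveSeed(seed, 11)),
    sensitivity = bootstrapCi(y, p, senM, n_boot, deriveSeed(seed, 12),
                              need_both_classes = TRUE),
    specificity = bootstrapCi(y, p, speM, n_boot, deriveSeed(seed, 13),
                              need_both_classes = TRUE))
  new("EvalReport", counts = c(TP = TP, FP = FP, TN = TN, FN = FN),
      metrics = metrics, ci = ci, roc = r$roc, auc = r$auc,
      cohort = cohort_tag, tissue = tissueType(cohort))
}

#' Transfer a trained model to a new cohort
#'
#' Step 1 ("unseen"): the frozen model is evaluated on the entire new
#' cohort — no weight, scaler or feature changes. Step 2: training is
#' warm-started from the frozen weights on the new cohort's training
#' split and the retrained model is evaluated on the new test split.
#' With `epochs = 0` the retrained model equals the frozen one and the
#' retrained report is just the unseen evaluation restricted to the
#' test split.
#'
#' @param model the source [TrainedEDNN].
#' @param cohort the new [VbmCohort] (same grid, mask and feature
#'   space as the source cohort).
#' @param split a [SplitPlan] on the new cohort.
#' @param config [ednnConfig()] for retraining; `max_epochs` may be 0.
#' @param n_boot,seed bootstrap settings for the reports.
#' @param cohort_tag tag for the reports.
#' @return list(unseen = EvalReport, model = TrainedEDNN,
#'   retrained = EvalReport).
#' @export
transferRetrain <- function(model, cohort, split, config = model@config,
                            n_boot = 2000L, seed = 1L,
                            cohort_tag = "transfer") {
  if (max(model@features@columns) > nVoxels(cohort))
    stop("feature mismatch between model and cohort", call. = FALSE)
  unseen <- evaluateModel(model, cohort, n_boot = n_boot, seed = seed,
                          cohort_tag = paste0(cohort_tag, "-unseen"))
  if (config$max_epochs >= 1L) {
    sub <- cohort[, match(split@train_ids, subjectIds(cohort))]
    retrained <- trainEDNN(sub, model@features, config, init = model)
  } else {
    retrained <- model
  }
  rep2 <- evaluateModel(retrained, cohort, subset = split@test_ids,
                        n_boot = n_boot, seed = seed,
                        cohort_tag = paste0(cohort_tag, "-retrained"))
  list(unseen = unseen, model = retrained, retrained = rep2)
}

#' Serialize an EvalReport to JSON
#'
#' Stable, timestamp-free JSON so identical runs produce byte-identical
#' reports.
#'
#' @param report an [EvalReport].
#' @param path output path.
#' @export
writeEvalReport <- function(report, path) {
  ci <- lapply(report@ci, function(x) as.numeric(x))
  obj <- list(cohort = report@cohort, tissue = report@tissue,
              counts = as.list(report@counts),
              metrics = report@metrics, ci95 = ci, auc = report@auc,
              roc = report@roc)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
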