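#' Run the full diagnostic pipeline on a cohort manifest
#'
#' End-to-end orchestration, per tissue: stratified split -> analysis
#' mask built from the *training* volumes only -> cohort stacking ->
#' mutual-information voxel selection on the training split -> network
#' training -> test-set evaluation -> group reference statistics ->
#' z-score saliency maps for test subjects. GM and WM are independent
#' models end-to-end; when both are run, their test-set probabilities
#' are averaged into a combined diagnosis report. All randomness derives
#' from `seed`, so a rerun with the same config is byte-identical.
#'
#' @param config named list (or path to a YAML/JSON file holding one)
#'   with elements: `manifest` (path or data.frame), `out_dir`, `seed`,
#'   `tissues` (subset of c("GM","WM")), `train_fraction`,
#'   `mask` (list(min_mean, min_variance)), `n_bins`, `k`,
#'   `ednn` (arguments to [ednnConfig()]), `n_boot`,
#'   `n_saliency` (test subjects to render).
#' @return (invisibly) list with per-tissue `models`, `reports`,
#'   `features`, the `split`, and `combined` when both tissues ran.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  cfg <- utils::modifyList(
    list(tissues = c("GM", "WM"), seed = 1L, train_fraction = 0.875,
         mask = list(min_mean = 0.1, min_variance = 1e-6),
         n_bins = 4L, k = 200L, ednn = list(), n_boot = 2000L,
         n_saliency = 3L, out_dir = NULL),
    config)
  manifest <- cfg$manifest
  if (is.character(manifest)) manifest <- readManifest(manifest)
  out <- cfg$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE,
                                recursive = TRUE)

  split <- splitCohort(manifest, cfg$train_fraction,
                       deriveSeed(cfg$seed, 1))
  message(sprintf("[split] %d train / %d test",
                  length(split@train_ids), length(split@test_ids)))

  res <- list(split = split, models = list(), reports = list(),
              features = list())
  test_probs <- list()
  test_labels <- NULL

  for (ti in seq_along(cfg$tissues)) {
    tissue <- cfg$tissues[ti]
    t0 <- Sys.time()
    pathcol <- if (tissue == "GM") "gm_path" else "wm_path"
    trainrows <- manifest[manifest$subject_id %in% split@train_ids, ]
    vols <- lapply(trainrows[[pathcol]], loadVolume)
    mask <- buildMask(vols, cfg$mask$min_mean, cfg$mask$min_variance)
    message(sprintf("[%s] mask: %d voxels", tissue, nVoxels(mask)))

    train <- stackCohort(manifest, tissue, mask,
                         subset = split@train_ids)
    test <- stackCohort(manifest, tissue, mask, subset = split@test_ids)

    scores <- miScores(train, cfg$n_bins)
    k <- min(cfg$k, nVoxels(mask))
    feats <- rankAndSelect(scores, k)
    message(sprintf("[%s] selected %d voxels, top MI %.4f nats",
                    tissue, k, feats@score[1]))

    ecfg <- do.call(ednnConfig,
                    utils::modifyList(
                      list(seed = deriveSeed(cfg$seed, 100 + ti)),
                      cfg$ednn))
    model <- trainEDNN(train, feats, ecfg)
    message(sprintf("[%s] trained %d epochs, training accuracy %.2f%%",
                    tissue, nrow(model@history),
                    100 * model@history$accuracy[nrow(model@history)]))

    report <- evaluateModel(model, test, n_boot = cfg$n_boot,
                            seed = deriveSeed(cfg$seed, 200 + ti),
                            cohort_tag = manifest$cohort[1])
    stats <- groupStats(train)

    res$models[[tissue]] <- model
    res$reports[[tissue]] <- report
    res$features[[tissue]] <- feats
    test_probs[[tissue]] <- predictProba(model, test)
    test_labels <- diagnosis(test)

    if (!is.null(out)) {
      saveVolume(VolumeImage(array(as.numeric(mask@mask),
                                   dim(mask@mask)), mask@affine),
                 file.path(out, sprintf("mask_%s.nii.gz", tissue)))
      writeMiScores(scores, file.path(out, sprintf("mi_%s.tsv", tissue)))
      saveEDNN(model, file.path(out, sprintf("model_%s.json", tissue)))
      writeEvalReport(report,
                      file.path(out, sprintf("report_%s.json", tissue)))
      utils::write.table(report@roc,
                         file.path(out, sprintf("roc_%s.tsv", tissue)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      nsal <- min(cfg$n_saliency, length(split@test_ids))
      for (sid in split@test_ids[seq_len(nsal)]) {
        map <- renderSaliency(model, unstackSubject(test, sid), stats,
                              mask, subject_id = sid)
        writeSaliency(map, file.path(out,
                                     sprintf("saliency_%s_%s.nii.gz",
                                             tissue, sid)))
      }
    }
    message(sprintf("[%s] done in %.1fs", tissue,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  if (length(test_probs) == 2L) {
    comb <- combineTissues(test_probs[["GM"]], test_probs[["WM"]])
    pred <- comb$label; y <- test_labels
    m <- confusionMetrics(sum(pred == 1 & y == 1),
                          sum(pred == 1 & y == 0),
                          sum(pred == 0 & y == 0),
                          sum(pred == 0 & y == 1))
    r <- rocAuc(comb$probability, y)
    res$combined <- list(metrics = m, auc = r$auc,
                         probability = comb$probability, label = pred)
    if (!is.null(out))
      jsonlite::write_json(list(metrics = m, auc = r$auc),
                           file.path(out, "report_combined.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(res)
}

#' Read a pipeline configuration file
#'
#' YAML (when the yaml package is installed) or JSON, by extension.
#'
#' @param path config file path.
#' @return named list.
#' @export
readPipelineConfig <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is needed for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
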