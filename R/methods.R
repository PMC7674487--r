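#' Accessors for vbmednn objects
#'
#' Small generics giving read access to the slots of the package's S4
#' classes without touching `@` directly.
#'
#' @param x an object.
#' @return `densityMatrix` returns the subjects x voxels matrix;
#'   `diagnosis` the integer 0/1 label vector; `subjectIds` the subject
#'   identifiers; `voxelCoords` an integer matrix of 1-based (i, j, k)
#'   grid coordinates; `tissueType` the tissue tag; `cohortMask` the
#'   [VoxelMask]; `nVoxels` the number of masked voxels;
#'   `selectedColumns` the ordered column indices of a
#'   [SelectedFeatures]; `miValues` the MI scores of an [MIScores] or
#'   [SelectedFeatures]; `reportMetrics` the named metric list of an
#'   [EvalReport].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("densityMatrix", function(x) standardGeneric("densityMatrix"))
#' @rdname accessors
#' @export
setGeneric("diagnosis", function(x) standardGeneric("diagnosis"))
#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @rdname accessors
#' @export
setGeneric("voxelCoords", function(x) standardGeneric("voxelCoords"))
#' @rdname accessors
#' @export
setGeneric("tissueType", function(x) standardGeneric("tissueType"))
#' @rdname accessors
#' @export
setGeneric("cohortMask", function(x) standardGeneric("cohortMask"))
#' @rdname accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))
#' @rdname accessors
#' @export
setGeneric("selectedColumns", function(x) standardGeneric("selectedColumns"))
#' @rdname accessors
#' @export
setGeneric("miValues", function(x) standardGeneric("miValues"))
#' @rdname accessors
#' @export
setGeneric("reportMetrics", function(x) standardGeneric("reportMetrics"))
#' @rdname accessors
#' @export
setGeneric("discriminativeMask", function(x) standardGeneric("discriminativeMask"))

#' @rdname accessors
setMethod("densityMatrix", "VbmCohort", function(x) t(assay(x, "density")))
#' @rdname accessors
setMethod("diagnosis", "VbmCohort", function(x) as.integer(colData(x)$label))
#' @rdname accessors
setMethod("subjectIds", "VbmCohort",
          function(x) as.character(colData(x)$subject_id))
#' @rdname accessors
setMethod("voxelCoords", "VbmCohort",
          function(x) as.matrix(rowData(x)[, c("i", "j", "k")]))
#' @rdname accessors
setMethod("tissueType", "VbmCohort", function(x) metadata(x)$tissue)
#' @rdname accessors
setMethod("cohortMask", "VbmCohort", function(x) metadata(x)$mask)

#' @rdname accessors
setMethod("nVoxels", "VoxelMask", function(x) sum(x@mask))
#' @rdname accessors
setMethod("nVoxels", "VbmCohort", function(x) nrow(x))

#' @rdname accessors
setMethod("selectedColumns", "SelectedFeatures", function(x) x@columns)
#' @rdname accessors
setMethod("miValues", "MIScores", function(x) x@score)
#' @rdname accessors
setMethod("miValues", "SelectedFeatures", function(x) x@score)
#' @rdname accessors
setMethod("reportMetrics", "EvalReport", function(x) x@metrics)
#' @rdname accessors
setMethod("discriminativeMask", "GroundTruth", function(x) x@mask)

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeImage %dx%dx%d, range [%.4g, %.4g]\n",
              d[1], d[2], d[3],
              min(object@data, na.rm = TRUE), max(object@data, na.rm = TRUE)))
})

setMethod("show", "VoxelMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("VoxelMask %dx%dx%d: %d voxels in mask (%.1f%% of grid)\n",
              d[1], d[2], d[3], sum(object@mask),
              100 * mean(object@mask)))
})

setMethod("show", "VbmCohort", function(object) {
  cat(sprintf("VbmCohort: %d subjects x %d voxels [%s]\n",
              ncol(object), nrow(object), tissueType(object)))
  tab <- table(factor(diagnosis(object), levels = 0:1,
                      labels = c("HC", "SCZ")))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  callNextMethod()
})

setMethod("show", "MIScores", function(object) {
  cat(sprintf(
    "MIScores: %d voxels, %d bins (%s), MI in [%.4f, %.4f] nats\n",
    length(object@score), object@n_bins, object@estimator,
    min(object@score), max(object@score)))
})

setMethod("show", "SelectedFeatures", function(object) {
  cat(sprintf("SelectedFeatures: top %d voxels, MI %.4f .. %.4f nats\n",
              length(object@columns), object@score[1],
              object@score[length(object@score)]))
})

setMethod("show", "TrainedEDNN", function(object) {
  cat(sprintf(
    "TrainedEDNN: %d features -> %d hidden -> 1 (logistic)\n",
    ncol(object@W1), nrow(object@W1)))
  last <- object@history[nrow(object@history), ]
  cat(sprintf("  %d epochs; final loss %.4f, training accuracy %.2f%%\n",
              nrow(object@history), last$loss, 100 * last$accuracy))
})

setMethod("show", "GroupStats", function(object) {
  cat(sprintf(
    "GroupStats [%s]: %d voxels (%d flagged), n HC=%d, SCZ=%d\n",
    object@tissue, length(object@mean_hc), sum(object@flagged),
    object@n_hc, object@n_scz))
})

setMethod("show", "SaliencyMap", function(object) {
  cat(sprintf("SaliencyMap for %s: %d defined, %d undefined voxels\n",
              object@subject_id, object@n_defined, object@n_undefined))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan: %d train / %d test (fraction %.4f, seed %d)\n",
              length(object@train_ids), length(object@test_ids),
              object@fraction, object@seed))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport [%s, %s]\n", object@cohort, object@tissue))
  cat(sprintf("  confusion: TP=%d FP=%d TN=%d FN=%d\n",
              object@counts["TP"], object@counts["FP"],
              object@counts["TN"], object@counts["FN"]))
  m <- object@metrics
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.2f", 100 * v))
  cat(sprintf("  accuracy %s%%  sensitivity %s%%  specificity %s%%\n",
              fmt(m$accuracy), fmt(m$sensitivity), fmt(m$specificity)))
  cat(sprintf("  PPV %s%%  NPV %s%%  NNP %s  AUC %.4f\n",
              fmt(m$ppv), fmt(m$npv),
              ifelse(is.na(m$nnp), "NA", sprintf("%.4f", m$nnp)),
              object@auc))
})
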