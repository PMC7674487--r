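#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' VolumeImage: a 3-D scalar volume with its voxel-to-world affine
#'
#' Minimal container for a spatially normalized tissue-density map: the
#' 3-D data grid (unitless densities, expected range roughly \[0, 1\]) and
#' the 4x4 voxel-to-world transform. Voxel indices are 1-based R array
#' indices; world coordinates come only from the affine.
#'
#' @slot data 3-D numeric array.
#' @slot affine 4x4 numeric voxel-to-world matrix; must be invertible.
#' @export
setClass("VolumeImage",
  representation(data = "array", affine = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3-D array")
    if (!all(dim(object@affine) == c(4L, 4L)))
      msg <- c(msg, "affine must be a 4x4 matrix")
    else if (!is.finite(det(object@affine)) || abs(det(object@affine)) < 1e-12)
      msg <- c(msg, "affine must be invertible")
    if (length(msg)) msg else TRUE
  }
)

#' VoxelMask: the analysis mask defining the voxelwise feature space
#'
#' A boolean grid marking which voxels enter the subjects-by-voxels matrix,
#' together with the grid's affine. Built by [buildMask()] from
#' across-subject mean and variance thresholds.
#'
#' @slot mask 3-D logical array.
#' @slot affine 4x4 voxel-to-world matrix of the grid the mask lives on.
#' @export
setClass("VoxelMask",
  representation(mask = "array", affine = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
      msg <- c(msg, "mask must be a 3-D logical array")
    if (sum(object@mask) < 1L)
      msg <- c(msg, "mask must contain at least one voxel")
    if (!all(dim(object@affine) == c(4L, 4L)))
      msg <- c(msg, "affine must be a 4x4 matrix")
    if (length(msg)) msg else TRUE
  }
)

#' VbmCohort: subjects-by-voxels density matrix with diagnosis labels
#'
#' The pipeline's central object, a [SummarizedExperiment] subclass. The
#' `"density"` assay is voxels x subjects (features in rows, Bioconductor
#' convention); `rowData` carries the (i, j, k) grid coordinate of each
#' masked voxel (1-based); `colData` carries `subject_id`, binary `label`
#' (0 = healthy control, 1 = patient) and the `cohort` tag. The
#' [VoxelMask] and tissue tag live in `metadata()`.
#'
#' Use [densityMatrix()] for the subjects x voxels orientation consumed by
#' the classifier, and [voxelCoords()], [diagnosis()], [tissueType()],
#' [cohortMask()] for the other components.
#'
#' @export
setClass("VbmCohort", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    cd <- colData(object)
    if (!all(c("subject_id", "label") %in% colnames(cd)))
      return("colData must contain subject_id and label")
    if (!all(cd$label %in% c(0L, 1L)))
      msg <- c(msg, "labels must be binary 0/1")
    if (anyDuplicated(cd$subject_id))
      msg <- c(msg, "subject_id must be unique")
    if (!all(c("i", "j", "k") %in% colnames(rowData(object))))
      msg <- c(msg, "rowData must contain voxel coordinates i, j, k")
    m <- metadata(object)$mask
    if (is.null(m))
      msg <- c(msg, "metadata must contain the VoxelMask")
    else if (nrow(object) != sum(m@mask))
      msg <- c(msg, "rows must correspond 1:1 to mask voxels")
    if (length(msg)) msg else TRUE
  }
)

#' PhantomSpec: parameterization of a synthetic two-group VBM cohort
#'
#' Describes a phantom cohort: grid, per-group size, spherical
#' "atrophy" blobs (center, radius, effect size in baseline-SD units by
#' which the patient group's density is reduced inside the blob, injected
#' before smoothing), baseline mean, noise SD, Gaussian smoothing FWHM in
#' voxels, RNG seed and tissue tag. Generation is bit-reproducible given
#' the seed.
#'
#' @slot grid_shape integer(3) grid extents.
#' @slot n_per_group subjects per group (>= 2).
#' @slot blobs data.frame with columns ci, cj, ck (1-based centers),
#'   radius (voxels), effect (>= 0, in units of `noise_sd`).
#' @slot baseline_mean,noise_sd,smooth_fwhm generation parameters.
#' @slot seed integer RNG seed.
#' @slot tissue tissue tag, "GM" or "WM".
#' @export
setClass("PhantomSpec",
  representation(grid_shape = "integer", n_per_group = "integer",
                 blobs = "data.frame", baseline_mean = "numeric",
                 noise_sd = "numeric", smooth_fwhm = "numeric",
                 seed = "integer", tissue = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@grid_shape) != 3L || any(object@grid_shape < 4L))
      msg <- c(msg, "grid_shape must be three extents >= 4")
    if (object@n_per_group < 2L)
      msg <- c(msg, "need at least 2 subjects per group")
    if (object@noise_sd <= 0)
      msg <- c(msg, "noise_sd must be > 0")
    b <- object@blobs
    if (nrow(b)) {
      if (any(b$effect < 0)) msg <- c(msg, "blob effects must be >= 0")
      ctr <- as.matrix(b[, c("ci", "cj", "ck")])
      lo <- sweep(ctr, 2, b$radius, "-") ; hi <- sweep(ctr, 2, b$radius, "+")
      if (any(lo < 1) || any(t(hi) > object@grid_shape))
        msg <- c(msg, "blobs must lie inside the grid")
    }
    if (length(msg)) msg else TRUE
  }
)

#' GroundTruth: the phantom's discriminative voxels
#'
#' Boolean grid of voxels inside any blob plus the per-voxel nominal
#' effect size; the oracle for feature-recovery tests.
#'
#' @slot mask 3-D logical array of discriminative voxels.
#' @slot effect 3-D numeric array of nominal per-voxel effect sizes.
#' @slot blobs the blob data.frame that generated it.
#' @export
setClass("GroundTruth",
  representation(mask = "array", effect = "array", blobs = "data.frame"),
  validity = function(object) {
    if (!identical(dim(object@mask), dim(object@effect)))
      return("mask and effect grids must align")
    TRUE
  }
)

#' MIScores: per-voxel mutual information with the diagnosis label
#'
#' Plug-in mutual information (nats) between each quantile-binned voxel
#' column and the binary label, with the voxel coordinates needed to map
#' columns back to the grid.
#'
#' @slot score numeric vector of MI values in nats (>= 0).
#' @slot coords integer matrix (n_voxels x 3) of 1-based grid coordinates.
#' @slot n_bins bins used for discretization.
#' @slot estimator estimator tag.
#' @export
setClass("MIScores",
  representation(score = "numeric", coords = "matrix",
                 n_bins = "integer", estimator = "character"),
  validity = function(object) {
    msg <- character()
    if (any(object@score < 0)) msg <- c(msg, "MI scores must be >= 0")
    if (nrow(object@coords) != length(object@score))
      msg <- c(msg, "coords must have one row per score")
    if (length(msg)) msg else TRUE
  }
)

#' SelectedFeatures: the top-k voxels by mutual information
#'
#' Ordered (descending MI, ties broken by ascending column index) voxel
#' column indices with their scores and grid coordinates.
#'
#' @slot columns integer vector of selected column indices (1-based).
#' @slot score MI score of each selected column, in nats.
#' @slot coords integer matrix (k x 3) of grid coordinates.
#' @slot n_bins bins used by the estimator that produced the scores.
#' @export
setClass("SelectedFeatures",
  representation(columns = "integer", score = "numeric",
                 coords = "matrix", n_bins = "integer"),
  validity = function(object) {
    msg <- character()
    k <- length(object@columns)
    if (k < 1L) msg <- c(msg, "at least one feature must be selected")
    if (length(object@score) != k || nrow(object@coords) != k)
      msg <- c(msg, "columns, score and coords must have equal length")
    if (is.unsorted(rev(object@score)))
      msg <- c(msg, "scores must be in descending order")
    if (length(msg)) msg else TRUE
  }
)

#' TrainedEDNN: the fitted two-layer classifier
#'
#' Weights and biases of the two fully connected layers (hidden ReLU,
#' logistic output), the selected features and feature scaler frozen at
#' training time, the training configuration and the per-epoch history.
#'
#' @slot W1 n_hidden x k weight matrix of the hidden layer.
#' @slot b1 hidden biases.
#' @slot W2 1 x n_hidden output weights.
#' @slot b2 output bias (length 1).
#' @slot features the [SelectedFeatures] the model was trained on.
#' @slot scaler list(center, scale) applied to inputs before the forward
#'   pass; frozen from the training split.
#' @slot config the [ednnConfig()] list used.
#' @slot history data.frame with one row per epoch (loss, penalty,
#'   accuracy).
#' @export
setClass("TrainedEDNN",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix",
                 b2 = "numeric", features = "SelectedFeatures",
                 scaler = "list", config = "list", history = "data.frame"),
  validity = function(object) {
    msg <- character()
    h <- nrow(object@W1)
    if (ncol(object@W1) != length(object@features@columns))
      msg <- c(msg, "W1 columns must match the number of selected features")
    if (length(object@b1) != h || ncol(object@W2) != h)
      msg <- c(msg, "hidden-layer shapes are inconsistent")
    if (nrow(object@W2) != 1L || length(object@b2) != 1L)
      msg <- c(msg, "output layer must be single-unit")
    if (nrow(object@history) < 1L)
      msg <- c(msg, "training history must be non-empty")
    if (length(msg)) msg else TRUE
  }
)

#' GroupStats: per-voxel reference distributions for saliency
#'
#' Sample mean and SD (denominator n-1) of density at every cohort voxel,
#' separately for healthy controls and patients, computed on a reference
#' (training) cohort. Voxels with zero SD in either group are flagged and
#' excluded from z-scoring.
#'
#' @slot mean_hc,sd_hc,mean_scz,sd_scz per-voxel statistics.
#' @slot flagged logical; TRUE where a group SD is zero (excluded).
#' @slot coords voxel grid coordinates (1-based).
#' @slot n_hc,n_scz group sizes.
#' @slot tissue tissue tag.
#' @export
setClass("GroupStats",
  representation(mean_hc = "numeric", sd_hc = "numeric",
                 mean_scz = "numeric", sd_scz = "numeric",
                 flagged = "logical", coords = "matrix",
                 n_hc = "integer", n_scz = "integer", tissue = "character"),
  validity = function(object) {
    n <- length(object@mean_hc)
    if (length(object@sd_hc) != n || length(object@mean_scz) != n ||
        length(object@sd_scz) != n || length(object@flagged) != n ||
        nrow(object@coords) != n)
      return("all per-voxel slots must have equal length")
    if (any(object@sd_hc[!object@flagged] <= 0) ||
        any(object@sd_scz[!object@flagged] <= 0))
      return("unflagged voxels must have positive SDs in both groups")
    TRUE
  }
)

#' SaliencyMap: a subject's combined z-score map
#'
#' The combined z-score rendered at the model's selected voxels
#' (background 0 elsewhere, NaN where the score is undefined because the
#' z-score denominator is near zero), as a [VolumeImage] plus bookkeeping.
#'
#' @slot volume the rendered [VolumeImage].
#' @slot subject_id subject identifier.
#' @slot n_defined,n_undefined counts of scored voxels.
#' @export
setClass("SaliencyMap",
  representation(volume = "VolumeImage", subject_id = "character",
                 n_defined = "integer", n_undefined = "integer"))

#' SplitPlan: a stratified train/test partition
#'
#' @slot train_ids,test_ids disjoint subject id vectors covering the
#'   cohort.
#' @slot fraction requested training fraction.
#' @slot seed RNG seed used.
#' @export
setClass("SplitPlan",
  representation(train_ids = "character", test_ids = "character",
                 fraction = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(intersect(object@train_ids, object@test_ids)))
      return("train and test ids must be disjoint")
    TRUE
  }
)

#' EvalReport: confusion counts, diagnostic metrics, ROC and AUC
#'
#' Holds the confusion matrix of a binary evaluation and the six
#' diagnostic quantities — accuracy, sensitivity, specificity, PPV, NPV and
#' NNP (number needed to predict, 1/(PPV+NPV-1)) — plus bootstrap 95% CIs
#' for accuracy/sensitivity/specificity, the ROC points and trapezoidal
#' AUC. Metrics whose denominator is zero (and NNP when PPV+NPV <= 1) are
#' `NA` rather than infinite.
#'
#' @slot counts named numeric: TP, FP, TN, FN.
#' @slot metrics named list of the six quantities (proportions in \[0,1\];
#'   NNP >= 1 when defined).
#' @slot ci named list of (lower, upper) 95% bounds.
#' @slot roc data.frame of (threshold, fpr, tpr) points.
#' @slot auc trapezoidal area under the ROC curve.
#' @slot cohort,tissue tags echoed from the evaluation.
#' @export
setClass("EvalReport",
  representation(counts = "numeric", metrics = "list", ci = "list",
                 roc = "data.frame", auc = "numeric",
                 cohort = "character", tissue = "character"),
  validity = function(object) {
    if (!all(c("TP", "FP", "TN", "FN") %in% names(object@counts)))
      return("counts must be named TP, FP, TN, FN")
    if (any(object@counts < 0))
      return("counts must be non-negative")
    TRUE
  }
)
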