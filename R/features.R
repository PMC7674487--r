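#' Quantile-discretize one voxel's densities
#'
#' Equal-frequency binning of a continuous column into `n_bins` codes
#' `0 .. n_bins-1`. Break points are the interior quantiles of the
#' values; a value equal to a break falls in the lower bin, so ties are
#' deterministic. A (near-)constant column degrades gracefully to a
#' single code 0 (its mutual information with any label is then 0).
#'
#' @param values numeric vector of per-subject densities.
#' @param n_bins number of bins (>= 2).
#' @return integer codes in `0 .. n_bins-1`.
#' @export
#' @examples
#' discretizeColumn(c(1, 2, 3, 4), 2)       # 0 0 1 1
#' discretizeColumn(c(5, 1, 3, 2, 4, 6), 3) # 2 0 1 0 1 2
discretizeColumn <- function(values, n_bins = 4L) {
  stopifnot(n_bins >= 2L, length(values) > 0L)
  probs <- seq_len(n_bins - 1L) / n_bins
  breaks <- unique(stats::quantile(values, probs, names = FALSE, type = 7))
  if (!length(breaks)) return(integer(length(values)))
  as.integer(rowSums(outer(values, breaks, ">")))
}

#' Plug-in mutual information between a discrete voxel and the label
#'
#' Empirical estimate, in nats, of
#' \deqn{I(X,Y) = \sum_x \sum_y \hat p(x,y) \log \hat p(y \mid x)
#'       - \sum_y \hat p(y) \log \hat p(y)}
#' over the joint contingency table, with the convention
#' \eqn{0 \log 0 = 0}. Tiny negative values from floating-point
#' cancellation are clipped to 0, so the estimate is always
#' non-negative and bounded by \eqn{H(Y) \le \log 2} for binary labels.
#'
#' @param x integer codes (e.g. from [discretizeColumn()]).
#' @param y binary labels of the same length.
#' @return mutual information in nats.
#' @export
#' @examples
#' mutualInformation(c(0, 0, 1, 1), c(0, 0, 1, 1))  # log(2)
mutualInformation <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (!length(x)) stop("empty input", call. = FALSE)
  if (!all(y %in% c(0L, 1L)))
    stop("labels must be binary 0/1", call. = FALSE)
  n <- length(x)
  tab <- table(x, y) / n
  px <- rowSums(tab); py <- colSums(tab)
  terms <- tab * log(tab / outer(px, py))
  mi <- sum(terms[tab > 0])
  max(mi, 0)
}

#' Mutual information of every voxel column with the diagnosis
#'
#' Quantile-bins each column of the cohort matrix and computes the
#' plug-in MI with the binary label. Inside the pipeline this runs on
#' the training split only, so the selected voxels are frozen before the
#' network ever sees test subjects.
#'
#' @param cohort a [VbmCohort].
#' @param n_bins quantile bins per column (default 4).
#' @return an [MIScores].
#' @export
miScores <- function(cohort, n_bins = 4L) {
  A <- assay(cohort, "density")  # voxels x subjects
  y <- diagnosis(cohort)
  score <- apply(A, 1L, function(v)
    mutualInformation(discretizeColumn(v, n_bins), y))
  new("MIScores", score = as.numeric(score), coords = voxelCoords(cohort),
      n_bins = as.integer(n_bins), estimator = "plugin-quantile")
}

#' Select the top-k voxels by mutual information
#'
#' Ranks columns by descending MI; ties are broken by ascending column
#' index so selection is deterministic.
#'
#' @param scores an [MIScores].
#' @param k number of voxels to keep (`1 <= k <= n_voxels`).
#' @return a [SelectedFeatures].
#' @export
rankAndSelect <- function(scores, k) {
  stopifnot(is(scores, "MIScores"))
  nv <- length(scores@score)
  if (k < 1L || k > nv)
    stop(sprintf("k must be in 1..%d", nv), call. = FALSE)
  ord <- order(-scores@score, seq_len(nv))[seq_len(k)]
  new("SelectedFeatures", columns = as.integer(ord),
      score = scores@score[ord],
      coords = scores@coords[ord, , drop = FALSE],
      n_bins = scores@n_bins)
}

#' Export MI scores as TSV
#'
#' One row per voxel: column index, grid coordinates and MI in nats.
#'
#' @param scores an [MIScores].
#' @param path output TSV path.
#' @export
writeMiScores <- function(scores, path) {
  df <- data.frame(column = seq_along(scores@score), scores@coords,
                   mi_nats = scores@score)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
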