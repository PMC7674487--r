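#' Per-voxel reference statistics by diagnosis group
#'
#' Sample mean and SD (denominator n-1) of density at every cohort voxel
#' for healthy controls and patients separately. Computed on the
#' training cohort so individual saliency maps are standardized against
#' distributions the model was fitted on. Voxels where either group has
#' zero SD are flagged and excluded from z-scoring.
#'
#' @param cohort a [VbmCohort] with at least 2 subjects per class.
#' @return a [GroupStats].
#' @export
groupStats <- function(cohort) {
  y <- diagnosis(cohort)
  if (sum(y == 0L) < 2L || sum(y == 1L) < 2L)
    stop("need at least 2 subjects per class for group statistics",
         call. = FALSE)
  A <- assay(cohort, "density")
  hc <- A[, y == 0L, drop = FALSE]; scz <- A[, y == 1L, drop = FALSE]
  rowSd <- function(M) {
    mu <- rowMeans(M)
    sqrt(pmax(rowSums((M - mu)^2), 0) / (ncol(M) - 1))
  }
  sd_hc <- rowSd(hc); sd_scz <- rowSd(scz)
  new("GroupStats", mean_hc = rowMeans(hc), sd_hc = sd_hc,
      mean_scz = rowMeans(scz), sd_scz = sd_scz,
      flagged = sd_hc == 0 | sd_scz == 0, coords = voxelCoords(cohort),
      n_hc = sum(y == 0L), n_scz = sum(y == 1L),
      tissue = tissueType(cohort))
}

#' The three saliency z-scores for a voxel value
#'
#' Standardizes a subject's voxel density against both reference
#' distributions and combines them:
#' \deqn{z_{HC} = \frac{v - \mu_{HC}}{\sigma_{HC}}, \quad
#'       z_{SCZ} = \frac{v - \mu_{SCZ}}{\sigma_{SCZ}}, \quad
#'       z = \frac{z_{SCZ}}{z_{SCZ} + z_{HC}}.}
#' The combined score is computed exactly as written — it is not bounded
#' to \[0, 1\] (the z-scores carry signs) — and is flagged undefined, not
#' infinite, when \eqn{|z_{SCZ} + z_{HC}| < \tau} (\eqn{\tau = 10^{-8}}).
#' All inputs are vectorized over voxels.
#'
#' @param v voxel value(s).
#' @param mean_hc,sd_hc,mean_scz,sd_scz reference statistics (SDs > 0).
#' @param tau denominator tolerance below which the combined score is
#'   undefined.
#' @return data.frame with `zscore_hc`, `zscore_scz`, `combined` (NaN
#'   where undefined) and logical `undefined`.
#' @export
#' @examples
#' subjectZscores(0.2, 0.5, 0.1, 0.3, 0.1)  # z_HC -3, z_SCZ -1, 0.25
subjectZscores <- function(v, mean_hc, sd_hc, mean_scz, sd_scz,
                           tau = 1e-8) {
  stopifnot(all(sd_hc > 0), all(sd_scz > 0))
  z_hc <- (v - mean_hc) / sd_hc
  z_scz <- (v - mean_scz) / sd_scz
  den <- z_scz + z_hc
  und <- abs(den) < tau
  comb <- ifelse(und, NaN, z_scz / den)
  data.frame(zscore_hc = z_hc, zscore_scz = z_scz, combined = comb,
             undefined = und)
}

#' Render a subject's combined z-score saliency map
#'
#' Writes the combined z-score at the model's selected voxels only
#' (saliency is tied to the voxels the classifier identified);
#' everything else is background 0. Selected voxels that are flagged in
#' the reference statistics or whose combined score is undefined get
#' NaN, and their count is reported on the returned object.
#'
#' @param model a [TrainedEDNN].
#' @param volume the subject's [VolumeImage], on the reference grid.
#' @param stats a [GroupStats] from the training cohort.
#' @param mask the [VoxelMask] the cohort was stacked with.
#' @param subject_id identifier recorded on the map.
#' @return a [SaliencyMap].
#' @export
renderSaliency <- function(model, volume, stats, mask,
                           subject_id = "subject") {
  stopifnot(is(model, "TrainedEDNN"), is(volume, "VolumeImage"),
            is(stats, "GroupStats"), is(mask, "VoxelMask"))
  if (!identical(dim(volume@data), dim(mask@mask)))
    stop("grid mismatch between subject volume and mask", call. = FALSE)
  out <- array(0, dim(mask@mask))
  cols <- model@features@columns
  if (!length(cols)) {
    warning("model has no selected voxels; saliency map is empty")
    return(new("SaliencyMap",
               volume = VolumeImage(out, mask@affine),
               subject_id = subject_id, n_defined = 0L,
               n_undefined = 0L))
  }
  cellidx <- which(mask@mask)[cols]
  v <- volume@data[cellidx]
  flagged <- stats@flagged[cols]
  comb <- rep(NaN, length(cols))
  ok <- !flagged
  if (any(ok)) {
    z <- subjectZscores(v[ok], stats@mean_hc[cols][ok],
                        stats@sd_hc[cols][ok],
                        stats@mean_scz[cols][ok],
                        stats@sd_scz[cols][ok])
    comb[ok] <- z$combined
  }
  out[cellidx] <- comb
  new("SaliencyMap", volume = VolumeImage(out, mask@affine),
      subject_id = subject_id, n_defined = sum(is.finite(comb)),
      n_undefined = as.integer(sum(!is.finite(comb))))
}

#' Write a saliency map and its JSON sidecar
#'
#' @param map a [SaliencyMap].
#' @param path output NIfTI path; the sidecar replaces the extension
#'   with `.json`.
#' @export
writeSaliency <- function(map, path) {
  saveVolume(map@volume, path)
  vals <- map@volume@data[is.finite(map@volume@data) &
                            map@volume@data != 0]
  side <- list(subject_id = map@subject_id, n_defined = map@n_defined,
               n_undefined = map@n_undefined,
               summary = if (length(vals))
                 list(min = min(vals), max = max(vals),
                      mean = mean(vals)) else NULL)
  jsonlite::write_json(side, sub("\\.nii(\\.gz)?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
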