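#' Read a spatially normalized tissue-density volume
#'
#' Loads a NIfTI-1 file (.nii or .nii.gz) into a [VolumeImage]. On-disk
#' integer data are returned on the scaled intensity scale (scl_slope /
#' scl_inter are applied by the reader). The image must be 3-D. VBM maps
#' are expected to be dense: by default any NaN in the data is an error;
#' with `nan_to_zero = TRUE` NaNs are replaced by 0 with a warning.
#'
#' @param path path to a readable NIfTI-1 file.
#' @param nan_to_zero replace NaN with 0 instead of erroring.
#' @return a [VolumeImage].
#' @seealso [saveVolume()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' saveVolume(VolumeImage(array(0.5, c(4, 4, 4))), f)
#' loadVolume(f)
loadVolume <- function(path, nan_to_zero = FALSE) {
  if (!file.exists(path))
    stop(sprintf("missing file: %s", path), call. = FALSE)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop(sprintf("unreadable NIfTI header in %s: %s",
                                 path, conditionMessage(e)), call. = FALSE))
  data <- as.array(img)
  stopIfNot3d(data, sprintf("image %s", basename(path)))
  if (anyNA(data)) {
    if (!nan_to_zero)
      stop(sprintf("NaN values in %s (set nan_to_zero = TRUE to zero them)",
                   path), call. = FALSE)
    warning(sprintf("%s: %d NaN voxels set to 0", basename(path),
                    sum(is.na(data))))
    data[is.na(data)] <- 0
  }
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  new("VolumeImage", data = array(as.numeric(data), dim(data)),
      affine = matrix(as.numeric(aff), 4, 4))
}

#' Construct a VolumeImage in memory
#'
#' @param data 3-D numeric array of densities.
#' @param affine 4x4 voxel-to-world matrix (default: identity spacing).
#' @return a [VolumeImage].
#' @export
VolumeImage <- function(data, affine = diag(4)) {
  new("VolumeImage", data = data, affine = affine)
}

#' Write a volume as NIfTI-1
#'
#' Inverse of [loadVolume()]: writes `float32` data with the affine stored
#' in both the qform and sform so it round-trips exactly.
#'
#' @param v a [VolumeImage].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
saveVolume <- function(v, path) {
  stopifnot(is(v, "VolumeImage"))
  img <- RNifti::asNifti(v@data)
  RNifti::pixdim(img) <- sqrt(colSums(v@affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(v@affine, code = 2L)
  RNifti::sform(img) <- structure(v@affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Build the analysis mask from a set of volumes
#'
#' Marks a voxel as in-mask when its across-subject mean is `>= min_mean`
#' and its across-subject variance is `> min_variance`. This defines the
#' high-dimensional feature space the classifier works in; inside the
#' pipeline it is computed on the training subjects only, so no test-set
#' information leaks into feature definition.
#'
#' @param volumes list of [VolumeImage] on identical grids (>= 2).
#' @param min_mean minimum across-subject mean density (>= 0).
#' @param min_variance variance must strictly exceed this (>= 0).
#' @return a [VoxelMask].
#' @export
buildMask <- function(volumes, min_mean = 0.1, min_variance = 1e-6) {
  if (length(volumes) < 2L)
    stop("need at least 2 volumes to build a mask", call. = FALSE)
  stopifnot(min_mean >= 0, min_variance >= 0)
  d <- dim(volumes[[1]]@data)
  aff <- volumes[[1]]@affine
  for (v in volumes) {
    if (!identical(dim(v@data), d))
      stop("grid mismatch between volumes", call. = FALSE)
  }
  n <- length(volumes)
  s <- array(0, d); s2 <- array(0, d)
  for (v in volumes) { s <- s + v@data; s2 <- s2 + v@data^2 }
  mu <- s / n
  va <- (s2 - n * mu^2) / (n - 1)
  va[va < 0] <- 0  # guard against rounding
  m <- (mu >= min_mean) & (va > min_variance)
  if (!any(m))
    stop("empty mask: no voxel passes the mean/variance thresholds",
         call. = FALSE)
  new("VoxelMask", mask = m, affine = aff)
}

#' Read or write a cohort manifest
#'
#' The manifest is a CSV with header
#' `subject_id,gm_path,wm_path,label,cohort`; labels are 0 (healthy
#' control) or 1 (patient). `readManifest` checks uniqueness of
#' subject ids, binary labels, and that every referenced file exists
#' (relative paths are resolved against the manifest's directory).
#'
#' @param path manifest CSV path.
#' @param check_files verify that referenced volumes exist.
#' @return a data.frame with the five manifest columns.
#' @export
readManifest <- function(path, check_files = TRUE) {
  if (!file.exists(path))
    stop(sprintf("missing manifest: %s", path), call. = FALSE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(subject_id = "character",
                                      cohort = "character"))
  need <- c("subject_id", "gm_path", "wm_path", "label", "cohort")
  if (!all(need %in% names(m)))
    stop("manifest must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  if (anyDuplicated(m$subject_id))
    stop("duplicate subject_id in manifest", call. = FALSE)
  if (!all(m$label %in% c(0L, 1L)))
    stop("manifest labels must be binary 0/1", call. = FALSE)
  base <- dirname(normalizePath(path))
  for (col in c("gm_path", "wm_path")) {
    rel <- !grepl("^(/|[A-Za-z]:)", m[[col]])
    m[[col]][rel] <- file.path(base, m[[col]][rel])
    if (check_files && !all(file.exists(m[[col]])))
      stop(sprintf("manifest references missing %s files", col),
           call. = FALSE)
  }
  m
}

#' @rdname readManifest
#' @param manifest a manifest data.frame.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble the subjects x voxels cohort matrix
#'
#' Loads every subject's volume for one tissue, restricts it to the mask
#' and stacks the masked densities into a [VbmCohort]. Row order of the
#' manifest is preserved as subject order; matrix column `c` holds the
#' density at the voxel whose grid coordinate is row `c` of
#' `voxelCoords()`.
#'
#' @param manifest manifest data.frame (see [readManifest()]).
#' @param tissue `"GM"` or `"WM"`.
#' @param mask a [VoxelMask]; all volumes must be on its grid.
#' @param subset optional subject ids to keep (in manifest order).
#' @return a [VbmCohort].
#' @export
stackCohort <- function(manifest, tissue = c("GM", "WM"), mask,
                        subset = NULL) {
  tissue <- match.arg(tissue)
  stopifnot(is(mask, "VoxelMask"))
  if (!all(manifest$label %in% c(0L, 1L)))
    stop("manifest labels must be binary 0/1", call. = FALSE)
  if (!is.null(subset))
    manifest <- manifest[manifest$subject_id %in% subset, , drop = FALSE]
  pathcol <- if (tissue == "GM") "gm_path" else "wm_path"
  d <- dim(mask@mask)
  keep <- which(mask@mask)
  X <- matrix(NA_real_, nrow = length(keep), ncol = nrow(manifest))
  for (s in seq_len(nrow(manifest))) {
    v <- loadVolume(manifest[[pathcol]][s])
    if (!identical(dim(v@data), d))
      stop(sprintf("grid mismatch for subject %s", manifest$subject_id[s]),
           call. = FALSE)
    X[, s] <- v@data[keep]
  }
  coords <- arrayInd(keep, d)
  colnames(coords) <- c("i", "j", "k")
  se <- SummarizedExperiment(
    assays = list(density = X),
    rowData = DataFrame(coords),
    colData = DataFrame(subject_id = manifest$subject_id,
                        label = as.integer(manifest$label),
                        cohort = manifest$cohort))
  colnames(se) <- manifest$subject_id
  metadata(se)$tissue <- tissue
  metadata(se)$mask <- mask
  as(se, "VbmCohort")
}

#' Rebuild a volume from one row of the cohort matrix
#'
#' Inverse of the masking in [stackCohort()]: scatter subject `s`'s masked
#' densities back onto the full grid (background 0).
#'
#' @param cohort a [VbmCohort].
#' @param s subject index or id.
#' @return a [VolumeImage].
#' @export
unstackSubject <- function(cohort, s) {
  if (is.character(s)) s <- match(s, subjectIds(cohort))
  m <- cohortMask(cohort)
  a <- array(0, dim(m@mask))
  a[m@mask] <- assay(cohort, "density")[, s]
  VolumeImage(a, m@affine)
}
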