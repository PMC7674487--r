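#' Specify a synthetic two-group VBM phantom cohort
#'
#' Builds a [PhantomSpec]. Each subject's volume is
#' `baseline_mean + smooth(noise)` where the noise field is i.i.d.
#' Gaussian with SD `noise_sd`; for patients the field is additionally
#' reduced by `effect * noise_sd` inside each spherical blob *before*
#' smoothing, so blob edges blur the way partial-volume effects blur real
#' atrophy. Values are clipped to \[0, 1\] (densities are proportions).
#'
#' @param grid_shape integer(3); default `c(24, 24, 24)` keeps a full
#'   pipeline run at desk scale.
#' @param n_per_group subjects per group.
#' @param blobs data.frame with columns `ci, cj, ck` (1-based centers),
#'   `radius` (voxels) and `effect` (density reduction in the patient
#'   group, in units of `noise_sd`). Default: one radius-3 blob of effect
#'   2 near the grid center.
#' @param baseline_mean,noise_sd,smooth_fwhm generation parameters
#'   (defaults 0.5, 0.1, 2.0 voxels FWHM).
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @param tissue tissue tag.
#' @return a [PhantomSpec].
#' @export
phantomSpec <- function(grid_shape = c(24L, 24L, 24L), n_per_group = 30L,
                        blobs = data.frame(ci = 12, cj = 12, ck = 12,
                                           radius = 3, effect = 2),
                        baseline_mean = 0.5, noise_sd = 0.1,
                        smooth_fwhm = 2.0, seed = 1L, tissue = "GM") {
  new("PhantomSpec", grid_shape = as.integer(grid_shape),
      n_per_group = as.integer(n_per_group), blobs = blobs,
      baseline_mean = baseline_mean, noise_sd = noise_sd,
      smooth_fwhm = smooth_fwhm, seed = as.integer(seed), tissue = tissue)
}

blobFields <- function(spec) {
  d <- spec@grid_shape
  ind <- array(FALSE, d); eff <- array(0, d)
  if (nrow(spec@blobs)) {
    gi <- slice.index(ind, 1); gj <- slice.index(ind, 2)
    gk <- slice.index(ind, 3)
    for (b in seq_len(nrow(spec@blobs))) {
      r2 <- (gi - spec@blobs$ci[b])^2 + (gj - spec@blobs$cj[b])^2 +
        (gk - spec@blobs$ck[b])^2
      inside <- r2 <= spec@blobs$radius[b]^2
      ind <- ind | inside
      eff[inside] <- pmax(eff[inside], spec@blobs$effect[b])
    }
  }
  list(indicator = ind, effect = eff)
}

#' Generate a phantom cohort on disk
#'
#' Writes `2 * n_per_group` NIfTI volumes per tissue (healthy controls
#' labeled 0, patients labeled 1), a manifest CSV, the ground-truth
#' discriminative mask as a 0/1 NIfTI and the blob specification as JSON.
#' When `wm_spec` is supplied the same subjects get an independent WM
#' volume set (its own noise stream); otherwise the WM paths simply reuse
#' the GM volumes so downstream two-tissue plumbing always has both
#' columns.
#'
#' @param spec a [PhantomSpec] for the GM volumes.
#' @param out_dir writable output directory (created if needed).
#' @param wm_spec optional [PhantomSpec] for WM volumes; must share
#'   `grid_shape` and `n_per_group` with `spec`.
#' @param cohort_tag cohort name written to the manifest.
#' @return list with `manifest` (data.frame, also written to
#'   `manifest.csv`), `ground_truth` (a [GroundTruth] for GM), and
#'   `ground_truth_wm` when `wm_spec` is given.
#' @export
generatePhantomCohort <- function(spec, out_dir, wm_spec = NULL,
                                  cohort_tag = "phantom") {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aff <- diag(c(2, 2, 2, 1))  # 2 mm isotropic grid
  n <- spec@n_per_group
  ids <- sprintf("sub-%03d", seq_len(2L * n))
  labels <- rep(c(0L, 1L), each = n)

  writeTissue <- function(tspec, prefix) {
    fb <- blobFields(tspec)
    shift <- -fb$effect * tspec@noise_sd  # injected before smoothing
    paths <- character(2L * n)
    withSeed(tspec@seed, {
      for (s in seq_len(2L * n)) {
        field <- array(stats::rnorm(prod(tspec@grid_shape),
                                    sd = tspec@noise_sd), tspec@grid_shape)
        if (labels[s] == 1L) field <- field + shift
        vol <- tspec@baseline_mean + gaussianSmooth3d(field,
                                                      tspec@smooth_fwhm)
        vol[vol < 0] <- 0; vol[vol > 1] <- 1
        paths[s] <- file.path(out_dir,
                              sprintf("%s_%s.nii.gz", ids[s], prefix))
        saveVolume(VolumeImage(vol, aff), paths[s])
      }
    })
    list(paths = paths,
         gt = new("GroundTruth", mask = fb$indicator, effect = fb$effect,
                  blobs = tspec@blobs))
  }

  gm <- writeTissue(spec, "gm")
  out <- list()
  if (!is.null(wm_spec)) {
    stopifnot(identical(wm_spec@grid_shape, spec@grid_shape),
              wm_spec@n_per_group == n)
    wm <- writeTissue(wm_spec, "wm")
    wm_paths <- wm$paths
    out$ground_truth_wm <- wm$gt
  } else {
    wm_paths <- gm$paths
  }

  manifest <- data.frame(subject_id = ids,
                         gm_path = basename(gm$paths),
                         wm_path = basename(wm_paths),
                         label = labels, cohort = cohort_tag,
                         stringsAsFactors = FALSE)
  writeManifest(manifest, file.path(out_dir, "manifest.csv"))
  saveVolume(VolumeImage(array(as.numeric(gm$gt@mask), spec@grid_shape),
                         aff),
             file.path(out_dir, "ground_truth_gm.nii.gz"))
  jsonlite::write_json(spec@blobs, file.path(out_dir, "blobs.json"),
                       digits = NA)
  manifest$gm_path <- file.path(out_dir, manifest$gm_path)
  manifest$wm_path <- file.path(out_dir, manifest$wm_path)
  c(list(manifest = manifest, ground_truth = gm$gt), out)
}

#' Map ground-truth voxels to cohort matrix columns
#'
#' Returns the column indices of the cohort matrix that fall inside a
#' phantom's discriminative blobs — the oracle set for feature-recovery
#' checks.
#'
#' @param gt a [GroundTruth].
#' @param mask the [VoxelMask] the cohort was stacked with.
#' @return integer vector of column indices (possibly empty).
#' @export
groundTruthColumns <- function(gt, mask) {
  stopifnot(is(gt, "GroundTruth"), is(mask, "VoxelMask"))
  if (!identical(dim(gt@mask), dim(mask@mask)))
    stop("grid mismatch between ground truth and mask", call. = FALSE)
  which(gt@mask[mask@mask])
}
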