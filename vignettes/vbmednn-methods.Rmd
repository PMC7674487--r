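---
title: "Methods: explainable neural-network classification of VBM maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explainable neural-network classification of VBM maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

vbmednn classifies subjects as patients or healthy controls (HC) from
voxel-based morphometry (VBM): spatially normalized gray-matter (GM)
and white-matter (WM) tissue-density volumes on a common grid,
typically 2 mm isotropic in MNI space. This vignette documents the
model, the numerical choices, and what the synthetic phantom cohorts
do and do not establish about real data.

## The data model

Each subject contributes one volume per tissue. An analysis mask —
voxels whose across-subject mean density is at least `min_mean` and
whose variance strictly exceeds `min_variance` — defines the feature
space; masked densities are assembled into a subjects × voxels matrix
(`VbmCohort`, a `SummarizedExperiment` with voxels as rows). The mask
is always computed on the training subjects only, so the definition of
the feature space never sees test data. GM and WM are processed as
fully independent models end to end; a combined diagnosis, when both
are available, is the arithmetic mean of the two predicted
probabilities thresholded at 0.5 (ties called as patient). Voxel
coordinates are 1-based R array indices throughout; world coordinates
come only from the NIfTI affine and no axis flips are ever applied.

## Mutual-information voxel selection

Whole-brain VBM easily has 10^5–10^6 masked voxels against a few
hundred subjects, so the classifier sees only the voxels most
informative about the diagnosis. Each voxel column is discretized into
`n_bins` equal-frequency (quantile) bins — robust to the skewness of
density values; ties fall deterministically into the lower bin and a
constant column degrades to a single code — and scored by the plug-in
mutual information with the binary label,

$$I(X,Y) = \sum_x \sum_y \hat p(x,y)\,\log \hat p(y \mid x)
         \;-\; \sum_y \hat p(y) \log \hat p(y),$$

in nats, with $0 \log 0 = 0$. The estimate is non-negative and bounded
by $H(Y) \le \ln 2$. The top `k` voxels (ties broken by ascending
column index) are frozen before training. Neither the bin count nor
`k` has a canonical value for this problem; the defaults are
`n_bins = 4` and `k = 200` at phantom scale (a few thousand voxels),
and both are exposed in the configuration and echoed into every run's
logs and model archive. MI is always computed on the training split
only — selecting voxels on data that later serves as the test set
would leak label information into the feature space.

## The classifier and its KL–L1 penalty

The network is deliberately small: the `k` selected voxels feed
`n_hidden` ReLU units (default 64) and a single logistic output.
Inputs are standardized by the training mean and SD per voxel; the
scaler is stored in the model. Training minimizes binary cross-entropy
plus a sparsity penalty on both weight matrices,

$$L(\theta) = \mathrm{BCE} + \lambda \sum_i \left[
  p_i \log\frac{p_i}{\varepsilon} +
  (1-p_i) \log\frac{1-p_i}{1-\varepsilon} \right],
  \qquad p_i = \mathrm{clip}(\lVert W_{i\cdot}\rVert_1,\ \delta,\ 1-\delta),$$

the Bernoulli KL divergence between each row's L1 norm and a target
sparsity $\varepsilon$ (default 0.05), with $\delta = 10^{-6}$. The
penalty is zero exactly when every clipped row norm equals
$\varepsilon$.

Two numerical choices make this penalty workable:

* **Initialization inside the domain.** The KL term is only defined
  for row norms in (0, 1). Conventional variance-scaled initialization
  puts row L1 norms far above 1 for realistic `k`, where the clipped
  penalty is flat and can never act. Rows are therefore initialized as
  random directions scaled to L1 norm 0.5, the middle of the domain.
* **Linearly extended gradient.** The exact gradient of the clipped
  penalty is zero outside $(\delta, 1-\delta)$, which makes leaving
  the domain irreversible. Training instead uses the gradient of the
  penalty extended linearly beyond the clip points (the boundary slope
  continued outward), so out-of-domain rows feel a restoring force.
  `klL1Penalty()` itself always evaluates the clipped formula exactly
  as written above.

With these two choices the mean distance between row L1 norms and
$\varepsilon$ decreases monotonically in $\lambda$ over a grid
spanning 0 to 10, while the default $\lambda = 10^{-3}$ leaves enough
capacity to fit a separable cohort perfectly. The weight $\lambda$,
width, activation, optimizer (Adam, learning rate 0.01, mini-batches
of 32), epoch cap and early-stopping patience have no canonical
published values; all sit in `ednnConfig()` and are recorded in the
model archive. Optimization is plain mini-batch Adam with analytic
backpropagation; all randomness (initialization, shuffling) derives
from the configured seed, and two runs with the same seed are
bit-identical. The model returned is the one with the best full-batch
training loss. The penalty covers both layers' weight matrices —
the parameter set of the loss is the whole network — and excludes
biases, whose row-norm semantics would be meaningless.

## Evaluation

Predictions threshold the output probability at 0.5 with ties called
patient. From the confusion counts the six standard quantities are
computed: accuracy, sensitivity TP/(TP+FN), specificity TN/(TN+FP),
PPV TP/(TP+FP), NPV TN/(TN+FN), and the number needed to predict

$$\mathrm{NNP} = \frac{1}{\mathrm{PPV} + \mathrm{NPV} - 1},$$

the reciprocal of the predictive summary index: the expected number of
subjects one must classify to add one net correct prediction beyond
chance. NNP is 1 for a perfect classifier and undefined (reported as
`NA`, never infinity) when PPV + NPV ≤ 1; any metric with a zero
denominator is likewise `NA`. ROC curves sweep the decision threshold
over the unique scores (tied subjects enter together) and AUC is the
trapezoidal integral, which equals the pairwise concordance
probability with ties counted ½.

Confidence intervals use a subject-level percentile bootstrap
(2.5/97.5 percentiles, `n_boot = 2000`, seeded); resamples that
collapse to a single class, where sensitivity or specificity is
undefined, are redrawn and counted. The bootstrap was chosen because
it is assumption-light and reproducible; it is known to be slightly
anticonservative for proportions at small n.

Cohort splits are stratified by diagnosis: the total training count is
`round(n · fraction)` and per-class counts are allocated by
largest-remainder rounding, keeping class proportions within one
subject of the target in both halves. A 400-subject balanced cohort at
fraction 0.875 splits exactly 350/50; a 132-subject (88/44) cohort at
fraction 92/132 splits exactly 92/40.

### Transfer to a new cohort

`transferRetrain()` first evaluates the frozen model on the entire new
cohort (the "unseen" report), then warm-starts training from the
frozen weights on the new cohort's training split and evaluates on its
test split. Retraining re-estimates the per-voxel input scaler on the
new training data — weights are inherited, preprocessing is not. This
matters: under a global density shift of a standard deviation or more,
a frozen scaler leaves every ReLU unit inactive and gradient-free, and
no amount of retraining can recover; re-centering restores the
gradient and lets the inherited weights adapt. Setting `max_epochs =
0` skips retraining entirely, so the retrained report reduces to the
frozen evaluation on the test split.

## Saliency z-score maps

For individual-level explanation, each selected voxel of a subject is
standardized against per-voxel reference statistics (mean and n−1 SD
per diagnosis group, computed on the training cohort; voxels with zero
SD in either group are flagged and excluded):

$$z_{HC} = \frac{v - \mu_{HC}}{\sigma_{HC}}, \qquad
  z_{SCZ} = \frac{v - \mu_{SCZ}}{\sigma_{SCZ}}, \qquad
  z = \frac{z_{SCZ}}{z_{SCZ} + z_{HC}}.$$

The combined score is computed exactly as written. Because the
z-scores carry signs, it is not confined to [0, 1] and its denominator
can vanish; whenever $|z_{SCZ} + z_{HC}| < 10^{-8}$ the voxel is
marked undefined (NaN in the exported NIfTI, counted in the JSON
sidecar) rather than allowed to blow up. A bounded variant (absolute
z-values) would produce prettier maps, but the unbounded form is the
one with a clean interpretation as a relative standardization, and
flagging keeps its pathologies explicit. Saliency is rendered only at
the model's selected voxels — the map explains the classifier, not the
whole brain — with background 0 elsewhere.

## The phantom generator

Real cohorts of this kind are restricted, so the package ships a
generator whose output exercises every pipeline stage against a known
ground truth. Each subject's volume is

$$v = \mathrm{clip}_{[0,1]}\left(\mu_0 + G_{\mathrm{fwhm}} *
      (\eta - s\,\sigma_\eta\,\mathbf{1}_{\mathrm{blob}}\,
      [\text{patient}])\right),$$

i.i.d. Gaussian noise $\eta$ (SD `noise_sd` = 0.1) around a baseline
$\mu_0$ = 0.5, with the patient group reduced by `effect` ($s$) noise
SDs inside spherical blobs *before* Gaussian smoothing (FWHM 2 voxels),
so lesion edges blur the way partial-volume effects blur real atrophy.
Densities are clipped to [0, 1] because tissue densities are
proportions. The defaults — a 24³ grid (13,824 voxels), one radius-3
blob (123 voxels) at effect 2.0, 30 subjects per group — define the
reference study conditions used by the tests and the acceptance
script: large enough that mutual information recovers the blob and the
network separates the groups, small enough that a full pipeline run
takes well under a minute. Generation is bit-reproducible from the
seed, and smoothing uses a separable truncated Gaussian kernel with
edge renormalization.

What the phantom does *not* emulate: brain anatomy and tissue
geometry, spatial covariance beyond isotropic smoothness, site and
scanner effects, registration error, age/sex structure, or
heterogeneous effect topographies across patients. Passing tests on
phantoms therefore establish that the algorithms are implemented
correctly and behave sensibly under controlled signal, noise and
drift — not that comparable accuracies would be obtained on clinical
cohorts.

## Problem sizes and runtime

The test suite and the acceptance script run everything at the
reference phantom scale: 24³ grids, 60-subject cohorts, top-200
voxels, 64 hidden units, ≤ 500 epochs; null-calibration and coverage
experiments use 10³–16³ grids and 200 simulated test sets of 50
subjects with 2000 bootstrap replicates. A complete suite finishes in
about a minute on a single CPU.

## Known limitations

* The plug-in MI estimator is biased upward at small n; ranking (the
  only use made of it) is unaffected, but reported nats should not be
  compared across different n.
* Univariate selection cannot find voxels that are informative only
  jointly.
* The combined z-score is undefined on a measure-zero set and
  heavy-tailed near it; maps should be read with its denominator in
  mind.
* The published description of the approach this package implements
  leaves $\varepsilon$, $\lambda$, layer widths and the selected voxel
  count unspecified; defaults here are explicit, logged choices, not
  reconstructions.
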