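# vbmednn

Diagnostic classification of structural-MRI voxel-based morphometry
(VBM) with an explainable two-layer neural network, for researchers
who have spatially normalized gray-/white-matter density maps (NIfTI,
one volume per subject per tissue on a shared grid) and a binary
diagnosis per subject.

The pipeline has three statistical ingredients:

1. **Mutual-information voxel selection.** Each masked voxel is
   quantile-binned and scored by the plug-in mutual information with
   the diagnosis label,
   *I(X,Y) = Σₓ Σ_y p̂(x,y) log p̂(y|x) − Σ_y p̂(y) log p̂(y)* (nats);
   the top-k voxels, frozen on the training split, become the
   classifier's inputs.
2. **A KL–L1-regularized two-layer network** (k voxels → ReLU hidden
   layer → logistic output) trained on cross-entropy plus
   λ Σᵢ [pᵢ log(pᵢ/ε) + (1−pᵢ) log((1−pᵢ)/(1−ε))], the Bernoulli KL
   divergence between each weight row's L1 norm pᵢ and a sparsity
   target ε.
3. **Z-score saliency maps** per subject over the selected voxels:
   z_HC = (v−μ_HC)/σ_HC, z_SCZ = (v−μ_SCZ)/σ_SCZ, combined
   z = z_SCZ/(z_SCZ+z_HC), exported as NIfTI overlays.

Evaluation reports the six binary diagnostic quantities — accuracy,
sensitivity, specificity, PPV, NPV and NNP (number needed to predict,
1/(PPV+NPV−1)) — with bootstrap 95% CIs, ROC/AUC, stratified cohort
splitting, and a transfer-retraining protocol (freeze → evaluate on an
unseen cohort → warm-start retrain on its training split) for moving a
model across cohorts. A synthetic phantom generator with known
discriminative blobs makes the whole pipeline testable without
clinical data; see `vignettes/vbmednn-methods.Rmd` for the model
details and design rationale.

## Worked example

Generate a phantom cohort (24³ grid, one radius-3 atrophy blob at
effect size 2.0, 30 subjects per group) and run the full pipeline:

```r
library(vbmednn)
ph  <- generatePhantomCohort(phantomSpec(seed = 7L), "phantom-demo")
res <- runPipeline(list(manifest = ph$manifest, tissues = "GM",
                        seed = 7L, out_dir = "phantom-demo/run"))
#> [split] 52 train / 8 test
#> [GM] mask: 13824 voxels
#> [GM] selected 200 voxels, top MI 0.6931 nats
#> [GM] trained 77 epochs, training accuracy 100.00%
res$reports$GM
#> EvalReport [phantom, GM]
#>   confusion: TP=4 FP=0 TN=4 FN=0
#>   accuracy 100.00%  sensitivity 100.00%  specificity 100.00%
#>   PPV 100.00%  NPV 100.00%  NNP 1.0000  AUC 1.0000
```

Reading the output: the analysis mask kept all 13,824 voxels (the
phantom varies everywhere); the best selected voxel reaches the
theoretical MI ceiling ln 2 ≈ 0.6931 nats (it splits the two groups
perfectly); training separates the cohort completely, and all 8
held-out subjects are classified correctly, so every rate is 100% and
NNP attains its minimum of 1 (one subject classified per net correct
prediction). At this effect size that is the expected outcome; shrink
`effect` in `phantomSpec()` to watch the metrics degrade. The run
directory contains the model archive (JSON), MI scores (TSV), the
evaluation report (JSON), ROC points (TSV) and per-subject saliency
overlays (NIfTI + JSON sidecar).

A thin CLI wraps the same functions:

```sh
exec/vbmednn simulate --out phantom-demo --seed 7
exec/vbmednn run --config config.json --seed 7 --out phantom-demo/run
```

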