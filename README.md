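# mgmtfuse

Non-invasive prediction of MGMT promoter methylation status in
glioblastoma from multiparametric MRI (mpMRI), for imaging scientists who
work with BraTS-style curated collections (registered T1, post-contrast
T1, T2 and FLAIR volumes plus a whole-tumor mask). MGMT methylation
predicts response to temozolomide; assaying it requires tissue, so an
imaging-based predictor is clinically attractive.

The package implements the full pipeline as tested, reusable R:

* **Preprocessing**: resampling to 1 mm³ on a 240×240×150 grid, 1st–99th
  percentile normalization to 0–255, a fixed 128×128 whole-tumor bounding
  box anchored at the tumor's minimum row/column over all slices, and
  slice-to-frame conversion into 150-frame clips — including a fifth
  *delta* channel, the voxelwise T1wCE − T1 subtraction computed before
  normalization.
* **Feature extraction**: a pluggable contract `clip -> 400 features`
  (off-the-shelf video-network descriptors); a deterministic stub
  extractor ships for offline work and testing.
* **The classifier**: a five-branch Siamese network — one shared encoder
  for all branches, additive self-attention that yields per-modality
  weights α (α ≥ 0, Σα = 1), and a sigmoid head on the attention-weighted
  embedding sum

      e_b = Enc(x_b),  s_b = uᵀ tanh(W e_b + c),  α = softmax(s),
      P(methylated) = σ( wᵀ Σ_b α_b e_b + b₀ )

  with missing modalities handled by masking their attention scores, and
  a 3-layer MLP (400→100→32→1, dropout 0.4) on the T1wCE branch as the
  baseline.
* **Evaluation**: 4×5-fold stratified cross-validation with mean ± SEM,
  exact Wilcoxon rank-sum comparisons, decision-curve analysis (net
  benefit), modality / extractor-network / delta-branch ablations on a
  shared split plan, external-cohort evaluation with reused fold models,
  and Lin's concordance correlation for cross-network feature
  reproducibility.
* **Synthetic data**: ellipsoid-tumor phantoms and class-conditional
  Gaussian feature cohorts with a known Bayes-optimal AUC
  (`pnorm(effect / sqrt(2))`), so every stage is testable without any
  image downloads.

Everything is tidyverse-shaped: cohorts are tibbles
(`subject_id, label, flair_f000..delta_t1_f399`), results come back as
tibbles with `tidy()` / `glance()` methods, and result objects plot via
`autoplot()`.

## Worked example

```r
library(mgmtfuse)

# a 585-subject cohort with a Mahalanobis-1.5 signal in the T1wCE branch
co   <- generate_feature_cohort(feature_cohort_config(seed = 1))
plan <- make_split_plan(co, k = 5, repetitions = 4, seed = 1)
fit  <- train_fusion(co, fusion_config(seed = 1))
predict_fusion(fit, co[1:3, ])
#> # A tibble: 3 x 7
#>   subject_id   prob alpha_flair alpha_t1 alpha_t2 alpha_t1wce alpha_delta_t1
#>   <chr>       <dbl>       <dbl>    <dbl>    <dbl>       <dbl>          <dbl>
#> 1 S0001      0.644     1.11e-10 1.11e-10 1.10e-10       1.000       1.10e-10
#> 2 S0002      0.0510    1.12e-10 1.12e-10 1.12e-10       1.000       1.11e-10
#> 3 S0003      0.170     1.12e-10 1.12e-10 1.11e-10       1.000       1.11e-10
```

`prob` is the predicted probability of a methylated promoter; the
`alpha_*` columns are the per-subject modality weights — here the model
has (correctly) learned to put essentially all of its attention on the
post-contrast T1 branch, where the cohort's signal lives.

A full cross-validation campaign:

```r
rep <- run_cross_validation(co, plan, "fusion", fusion_config(seed = 1))
glance(rep)[, c("auc_mean", "auc_sem")]
#> # A tibble: 1 x 2
#>   auc_mean auc_sem
#>      <dbl>   <dbl>
#> 1    0.780  0.0164
```

against the analytic Bayes bound `pnorm(1.5 / sqrt(2)) = 0.856` for this
generator setting. `autoplot(rep)` shows the fold-level spread,
`plot_attention_weights(rep)` the average modality weights, and
`decision_curve()` + `autoplot()` the net-benefit analysis.

The phantom-image side:

```r
subj <- generate_phantom_subject(phantom_config(seed = 1))
prep <- preprocess_subject(subj$volumes, subj$mask)   # five 150x128x128 clips
row  <- assemble_subject(prep$clips, "stub", "PH001", label = 1L)
```

A thin command-line wrapper for the same operations is installed at
`inst/cli/mgmtfuse` (`synth-phantom`, `synth-cohort`, `preprocess`,
`extract`, `cv`).

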