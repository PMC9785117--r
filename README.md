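# metaboaging

Serum metabolomics analysis of chronological aging in adult cohorts: which
metabolites track age after adjusting for BMI, which pathways they point
to, how much of the age variation they jointly explain, and *when* the
metabolome changes course — the "aging metabolism breakpoint".

The package is aimed at metabolomics analysts working with cohort tables
(subjects × variables: age, sex, BMI, clinical chemistry, NMR- and
LC-HRMS-derived metabolite concentrations). It implements the full
analysis chain as separately testable modules plus a reproducible
pipeline, and ships a calibrated synthetic cohort generator so everything
can be exercised, validated and benchmarked without access to
subject-level data.

## The statistical core

* **Feature QC** — LC-HRMS feature inclusion (mean blank < 5% of mean
  sample signal; QC CV% < 20% with triplicates averaged first;
  missingness < 10%) and QC-anchored LOESS drift normalization: per
  feature, a degree-1 LOESS of QC intensity vs injection order is
  evaluated at every injection and intensities are divided by
  `curve / median(QC)`.
* **Preprocessing** — iterative conditional-normal multiple imputation
  (m = 5, averaged); per-variable Box-Cox transform with λ chosen on a
  grid over [−10, 10] to minimize the SD of the geometric-mean-scaled
  transform z(λ) = (yᵡ − 1)/(λ·GM^(λ−1)); standardization anchored to the
  training arm (the same λ, mean and SD are applied to the test arm).
* **Screening** — BMI-adjusted partial Pearson correlation of every
  variable with age (`r` of the two OLS residual vectors,
  `df = n − 2 − k`), significant only if raw p < 0.05 **and** rejected by
  Benjamini–Hochberg step-up at FDR q = 0.2.
* **Enrichment** — upper-tail hypergeometric over-representation of the
  significant metabolite set, with enrichment ratio = hits / expected
  hits (expected = query·pathway/universe).
* **Age model** — forward stepwise OLS of age on the retained
  metabolites, BMI forced in, entry at partial-F p < 0.05, VIF
  diagnostics, and cross-validation as the predicted–observed correlation
  on a held-out ~25% test arm.
* **Breakpoint** — PCA (correlation matrix; loadings =
  eigenvector·√eigenvalue) of the retained metabolites + BMI; PC1 scores
  vs age are partitioned at every admissible split (minimum segment
  ⌊n/3⌋), two lines fitted per split, and the split maximizing
  r²₁ · r²₂ chosen; the lines' intersection is the breakpoint age.

## Worked example

```r
library(metaboaging)
cfg <- pipeline_config(generator = generator_config(seed = 1), seed = 1)
s <- run_pipeline(cfg, "run1")
s$significant
```

```
              variable partial_r    p_raw
1               valine    -0.451 1.40e-06
2           isoleucine    -0.437 3.11e-06
3 3-hydroxyisobutyrate    -0.429 5.00e-06
4              leucine    -0.385 4.96e-05
5            ornithine     0.311 1.24e-03
6           tryptophan    -0.302 1.71e-03
7               lc_034     0.272 4.96e-03
```

Seven variables pass the dual rule on this cohort's training arm
(n = 105): the branched-chain amino acids, 3-hydroxyisobutyrate and
tryptophan decline with age, ornithine rises, and one LC-HRMS null
feature slips in — the kind of false positive an FDR of 0.2 tolerates.

```r
s$enriched_pathways
```

```
                                     pathway hits expected enrichment_ratio  p_hyper
1 Valine, Leucine and Isoleucine Degradation    4    0.571                7 0.000357
```

The significant set is 7-fold over-represented in BCAA degradation
(4 hits where 0.57 were expected by chance).

```r
s$model$selected            # "valine"
s$model$r_multiple_train    # 0.478
s$model$r_multiple_test     # 0.326
s$breakpoint$intersection_age  # 36.9
```

Forward stepwise (BMI forced) retains valine; the model correlates 0.478
with age on the training arm and 0.326 on the held-out test arm. The
two-segment search on PC1 scores (PC1 carries 64% of the variance of the
retained metabolites + BMI) places the breakpoint at 36.9 years on this
cohort — the generator planted its hinge at 32, and the recovery study in
the vignette quantifies how noisy and late-biased this single-cohort
estimate is.

All stage outputs (`cohort.tsv`, `preprocessed.tsv`, `boxcox_specs.tsv`,
`associations.tsv`, `enrichment.tsv`, `model.json`, `breakpoint.json`,
`summary.json`, `run_log.txt`) are plain text in `run1/`, re-loadable with
the package's own readers, and byte-identical across reruns with the same
seed.

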