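# radiopcr

Multimodal radiomics prediction of pathological complete response (pCR) to
neoadjuvant chemoradiotherapy in locally advanced rectal cancer.

About 11% of rectal-cancer patients treated with chemoradiotherapy before
surgery turn out to have no residual tumor in the surgical specimen
(ypT0 ypN0). `radiopcr` implements, as tested R code, a complete
two-institution workflow for predicting that response from pre-treatment
imaging (T2-weighted MRI, diffusion MRI, contrast-enhanced CT) plus clinical
covariates:

1. **3D feature extraction** from NIfTI volume/mask pairs — 15 shape, 11
   intensity-histogram and 62 texture features (GLCM/GLRLM/GLSZM/NGTDM,
   single merged matrix over all 13 directions at distance 1 voxel), under
   linear and histogram-equalized fixed-bin-number discretization at 32 and
   64 bins: 274 features per image, 822 per 3-modality patient.
2. **ComBat harmonization** — parametric empirical-Bayes location/scale
   removal of institution effects, fitted on the pooled feature table
   before any selection (outcome labels never used); cross-checked against
   `sva::ComBat`.
3. **Feature selection** on the training institution only: univariate
   Mann–Whitney AUC ≥ 0.60, then greedy Spearman de-correlation (|ρ| ≤ 0.7,
   higher-AUC feature wins).
4. **SMOTE** oversampling of the pCR class to 1:1, a single-hidden-layer
   neural network (`nnet`), bootstrap out-of-bag internal validation, and a
   probability cutoff locked by maximizing the Youden index
   *YI = Se + Sp − 1* on training scores.
5. **Frozen-cutoff external evaluation** on the testing institution:
   sensitivity, specificity, balanced accuracy *Bacc = (Se+Sp)/2*,
   Mann–Whitney AUC p-values, decision-curve analysis, and
   segmentation-robustness replay with simulated second-observer masks
   (Dice-calibrated).

Because the corresponding clinical cohorts are not publicly deposited, the
package includes a first-class synthetic cohort generator
(`generate_cohort()`) reproducing the statistical structure the analysis
assumes — two institutions (64/60 patients, 9/5 pCR events),
class-dependent lesion shape and texture, institution-dependent intensity
effects, clinically correlated covariates — so the entire pipeline runs and
is tested without any download.

## Worked example

```r
library(radiopcr)

cohort <- generate_cohort(cohort_config(), seed = 1)
cohort
#> <synthetic_cohort> 124 patients (64 train / 60 test), 14 pCR (11.3%)

experiment <- run_experiment(cohort, seed = 1)
experiment
#> pCR prediction experiment (seed 1)
#>
#> Training cohort:
#>            Model AUC       p Cutoff_pct Se_pct Sp_pct Bacc_pct
#>         Clinical   1 1.6e-06         51    100    100      100
#>         Radiomic   1 1.8e-06         50    100    100      100
#>         Combined   1 1.8e-06         50    100    100      100
#>  ComBat_Radiomic   1 1.8e-06         50    100    100      100
#>  ComBat_Combined   1 1.8e-06         50    100    100      100
#>
#> Testing cohort (frozen cutoffs):
#>            Model  AUC       p Cutoff_pct Se_pct Sp_pct Bacc_pct
#>         Clinical 0.84 0.01300         51     60   85.5     72.7
#>         Radiomic 1.00 0.00024         50     80  100.0     90.0
#>         Combined 1.00 0.00023         50     80  100.0     90.0
#>  ComBat_Radiomic 1.00 0.00024         50    100  100.0    100.0
#>  ComBat_Combined 1.00 0.00024         50    100  100.0    100.0
```

The flexible network separates every training cohort perfectly (which is
why the cutoff is locked on training scores and all conclusions rest on
the held-out institution); on the testing institution a generalization gap
opens, radiomics adds to the clinical model, and the harmonized models
transfer best. Exact numbers vary with the seed — across 20 master seeds
the mean test Bacc was 64.8% (Clinical) vs 95.5% (ComBat_Combined), with
the harmonized combined model ahead in 20/20 runs. Each row mirrors the
standard report layout: AUC with a
Mann–Whitney p-value, the locked cutoff in percent, and
sensitivity/specificity/balanced accuracy at that cutoff. `summary()` on a
fitted `pcr_model` shows the retained features, the cutoff and the
bootstrap out-of-bag AUC; `write_experiment()` emits feature tables,
selection audit, per-model JSON and decision-curve CSVs;
`evaluate_robustness()` re-scores the pre-trained models on
second-observer masks. A thin command-line wrapper is available:
`Rscript scripts/run_pipeline.R --seed 1 --out runs/demo`.

Individual stages are exported and composable: `read_volume()` /
`read_mask()`, `extract_patient()`, `fit_combat()` / `apply_combat()`,
`select_features()`, `smote_balance()`, `pcr_model()`, `youden_cutoff()`,
`classification_metrics()`, `decision_curve()`.

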