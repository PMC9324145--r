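# perfrad

Temporal radiomics of DSC perfusion MRI for ischemic stroke outcome
prediction.

## The problem

The 90-day modified Rankin Scale (mRS, 0 = no symptoms … 6 = death) is
the standard functional endpoint after ischemic stroke. Predicting it at
admission supports treatment planning. Two sources are available: tabular
clinical covariates (CTI — age, sex, NIHSS scores, symptoms,
comorbidities, lesion volume) and the DSC-PWI perfusion series, a 4D MRI
volume sequence in which a contrast bolus transiently darkens perfused
tissue. Hypoperfused lesion tissue (LT) dips less and later than its
mirrored contralateral normal tissue (NT) — a temporal signature that
static perfusion maps discard.

`perfrad` implements the full analysis as a tested R package:

1. **Temporal radiomics** — each series is smoothed (triple moving
   average along time), decomposed into its 50 volumes `S(n)`, and 1316
   features per timepoint are extracted per ROI (14 shape + 18
   first-order + 24 GLCM + 16 GLRLM + 16 GLSZM + 5 NGTDM + 14 GLDM on the
   original image, plus the 93 non-shape features on 5
   Laplacian-of-Gaussian and 8 Haar-wavelet images), named
   `base_n`, 65,800 columns per series. Texture matrices are accumulated
   in compiled code; formulas follow the standard IBSI-style definitions.
2. **Significance filter** — features are normalized as
   `(x − x̄)/(max − min)` and kept when a Levene-gated two-sample t-test
   (pooled vs Welch) between LT and NT rows gives raw p < 0.05.
3. **Thirteen selectors** — MIM, MIFS, MRMR, JMI, CMIM (greedy mutual
   information), Fisher, Laplacian score, ReliefF, F-score, T-score,
   MCFS, alpha investing, Lasso; Lasso keeps |β| > 0.02, the rest keep
   min–max-normalized scores > 0.9, all capped at 20 features.
4. **Composite-score benchmark** — each feature set runs stratified
   tenfold cross-validation on ten classifier families (SVM, DT,
   AdaBoost, NN, RF, KNN, LR, LDA, GBDT, naive Bayes);
   `CS = (1/KM) Σ_{k,m} index(k, model(m))` over K = 5 indexes
   (Pre, Acc, Auc, F1, Recall) and M = 10 models picks `best_method`.
5. **Survival fusion** — the winner selects mRS radiomics features
   (mRSRF); CTI + mRSRF train a feed-forward Cox partial-likelihood
   scorer (age as event time, poor outcome mRS ≥ 3 as event, 4000 epochs,
   batch 20, Breslow ties) whose range-normalized risk is the survival
   feature SurvF.
6. **Outcome evaluation** — seven groups (CTI, mRSRF, SurvF and their
   four fusions) × ten models × three granularities (mRS_7, mRS_4
   0/1–2/3–4/5–6, mRS_2 good 0–2 / poor 3–6) on a stratified 70/30
   split.

A synthetic-cohort generator stands in for the private hospital data:
gamma-variate bolus curves with a smaller, delayed lesion dip, clinical
marginals matching the published cohort statistics (age 71.4 ± 10.9,
26.8% female, …), and mRS labels with a plantable dependence on clinical
and imaging covariates (priors 25/11/9/4/8/9/14 over 80 sets). See the
methods vignette (`vignettes/methods.Rmd`) for every model, default and
assumption.

## Worked example

```r
library(perfrad)

cfg <- pipeline_config(
  seed = 2026, outdir = "run",
  synth = list(n_patients = 80, n_timepoints = 50,
               volume_shape = c(6, 16, 16)),
  radiomics = list(enabled_classes = "First-order"),
  survival = list(epochs = 1000))
res <- run_pipeline(cfg)
#> [perfrad] cohort: 80 series, volume 6x16x16
#> [perfrad] features: 160 samples x 900 columns
#> [perfrad] significant: 256 / 900 columns
#> [perfrad] best method: Fisher (CS = 0.999)
#> [perfrad] outstanding features: 59
#> [perfrad] mRS_2: mRSRF 3 features, SurvF training C-index 1.000
res$situations$mRS_2$evaluation$group_means
#>         group  mAuc  mAcc  mPre   mF1 mRecall
#>           CTI 0.739 0.676 0.693 0.648   0.652
#>         mRSRF 0.683 0.672 0.697 0.638   0.646
#>         SurvF 0.508 0.556 0.460 0.466   0.527
#>     CTI+mRSRF 0.794 0.720 0.748 0.697   0.697
#>     CTI+SurvF 0.749 0.688 0.708 0.659   0.663
#>   mRSRF+SurvF 0.671 0.696 0.713 0.672   0.673
#>           ALL 0.787 0.728 0.764 0.694   0.700
```

Reading: 160 tissue samples (80 LT + 80 NT) enter the filter; ~28% of
temporal features separate lesion from normal tissue. On this synthetic
cohort the LT/NT task saturates, so several composite scores tie near
0.999 and the alphabetical tie-break names the winner (Fisher here). In
the good/poor evaluation the fused groups beat clinical covariates alone
(mAuc 0.79 vs 0.74) because the generator plants part of the outcome
signal in the perfusion deficit — the qualitative pattern the method is
designed to exploit. Exact numbers vary with the seed; a single 70/30
split at n = 80 is intentionally faithful to the small-cohort design and
correspondingly noisy.

The same computation is laid out as a narrated workflow under
`analysis/` (`01_simulate_cohort.R` … `07_full_pipeline.R`), each stage
writing its tables to `results/`.

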