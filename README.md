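# resteeg

Resting-state EEG biomarkers from source-patch signals, with honest
multivariate evaluation.

## The problem

Psychiatric-biomarker studies commonly extract large batteries of
resting-state EEG features — spectral power, oscillatory peaks, 1/f
slopes, long-range temporal correlations, functional connectivity — and
ask whether any of them separates a clinical group from a comparison
group, either univariately or through machine learning. Two things
routinely go wrong: age effects masquerade as group effects when the
groups differ in age, and cross-validated "validation" accuracies are
reported from the same data that tuned the model, which inflates them
badly when features outnumber subjects.

`resteeg` implements the full workflow for 68-patch
(Desikan–Killiany) source-level recordings:

1. **Signal preparation** — zero-phase band-pass/notch filtering,
   resampling, 4-s epoching, a minimum-duration rule, and polarity-aligned
   collapsing of vertex signals into patch signals.
2. **Feature battery (3443 per recording)** — 680 band powers
   (absolute/relative in delta 1.25–4, theta 4–8, alpha 8–13, beta 13–30,
   gamma 30–48 Hz), 30 hemispheric asymmetries, 6 theta/beta ratios,
   69 peak alpha frequencies, 68 aperiodic (1/f) exponents; 345 DFA
   exponents and 345 fEI values (per patch + global, per band); 1900
   connectivity features (coherence, imaginary coherence, PLV, wPLI,
   orthogonalized power-envelope correlation over 76 region-level
   connections × 5 bands).
3. **Age screening and detrending** — per-feature Pearson correlation
   with age, BH-FDR within each of 12 feature types, whole-cohort OLS
   detrending of flagged (family × band) subgroups.
4. **Group statistics** — permutation tests on means, Levene's test on
   variances, FDR within type; a type counts as significant when more
   than 5% of its features survive correction.
5. **Prediction** — mRMR per feature type feeding lasso/ridge logistic
   regression, linear SVM with RFE, random forest (classification) or
   penalized linear regression (questionnaire scores), inside a
   stratified **two-layer** cross-validation (default 10 repetitions ×
   10 outer × 10 inner folds = 100 final models) scored by balanced
   accuracy `(sensitivity + specificity)/2` or normalized MAE
   `MAE(model)/MAE(train-mean predictor)`.
6. **Synthetic cohorts** — a generator with exact power-law backgrounds,
   controllable oscillatory peaks, fractional-Gaussian-noise envelopes
   (known Hurst/DFA exponents), controllable pairwise coupling, realistic
   two-group demographics, and injectable age trends and group effects —
   every parameter stored as ground truth for estimator validation.

## Worked example

```r
library(resteeg)

# a small two-group cohort: 12 + 12 subjects, 120 s at 500 Hz, 4 patches,
# with a strong alpha-amplitude group effect (Cohen's d = 2)
cfg <- synth_config(seed = 7, n_con = 12, n_asd = 12, duration_s = 120,
                    n_patches = 4, group_effect = c(amp_alpha = 2))
cohort <- generate_cohort(cfg, return_recordings = FALSE)

ft <- extract_cohort_features(cohort)
ft
#> <feature_table> 24 subjects x 261 features
#>   per type: aperiodic=4, asymmetry=10, coh=30, dfa=25, fei=25, imcoh=30,
#>   paf=5, pec=30, plv=30, power=40, tbr=2, wpli=30

scr <- age_screen(ft)
ft <- detrend_age(ft, scr)

st <- group_stats(ft, n_perm = 2000, seed = 7)
st
#> <group_stats> significant features (adjusted p < 0.05 ):
#>   power      mean: 27/40  variance: 0/40
#>   ...
#>   aperiodic  mean: 4/4  variance: 0/4
#>   dfa        mean: 0/25  variance: 0/25
#>   ...

cv <- run_two_layer_cv(ft, "group", models = "logistic_l1",
                       grid = reduced_grid(), repeats = 2,
                       outer_k = 4, inner_k = 3, seed = 7)
cv
#> <cv_report> classification, 2 repeats x 4 outer folds (1 models/row)
#>   logistic_l1  test balanced accuracy 0.604 [0.518, 0.690], validation 0.729, p(baseline) 0.18
```

Reading the output: 27 of the 40 power features carry the injected
alpha-amplitude effect after FDR (the aperiodic exponents shift too — a
strong alpha peak biases the 1/f fit, a realistic cross-contamination),
yet the cross-validated classifier on 24 subjects reaches only 60%
balanced test accuracy while its *validation* accuracy — the quantity
tuned on — looks like 73%. That validation–test gap on a small cohort is
precisely the phenomenon the two-layer scheme exists to expose; at
larger cohort sizes (say 80 subjects at 300 s) the same d = 2 effect
yields test accuracies above 80%.

`run_pipeline(run_config(...))` wires the stages together and writes the
feature table, screening report, statistics, CV report and a manifest
into a run directory.

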