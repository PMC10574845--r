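# ppgbp

Cuff-less blood-pressure estimation from photoplethysmography, end to
end, in R.

Continuous non-invasive monitoring of systolic and diastolic blood
pressure (SBP/DBP) is possible because the shape of the optical pulse
wave recorded by a PPG sensor co-varies with arterial pressure. `ppgbp`
is for researchers in biomedical signal processing and digital health
who want a complete, testable implementation of the morphology-based
regression approach:

* **Conditioning** of paired 125 Hz PPG/ABP records: channel alignment,
  0.5–10 Hz zero-phase band-pass, Z-score standardization, baseline
  correction, foot-to-foot pulse segmentation, quality and
  shape-similarity gating, per-pulse SBP/DBP labeling from the ABP
  extrema, and the physiologic range filter (SBP 80–180, DBP
  60–110 mmHg).
* **MODWT pulse enhancement**: an undecimated wavelet multiresolution
  analysis (`sym4`, 4 levels) whose additive components reconstruct the
  signal exactly; dropping the finest detail denoises without shifting
  fiducials.
* **Morphology features**: a fixed registry of 154 named features
  (fiducial amplitudes/times, areas split at the dicrotic notch,
  `ln(1 + position)` non-linearities, sample statistics, first/second
  derivatives with the SDPPG a–e waves, single-pulse DFT harmonics) on
  both the raw and the enhanced pulse.
* **Feature selection**: greedy mRMR ranking (mutual-information
  difference scheme) with the retained count fixed by the RReliefF
  importance threshold (scores strictly above 0.001).
* **Models**: XGBoost tuned by Gaussian-process Bayesian optimization
  (expected improvement; 7-fold search CV, 10-fold training CV, stored
  [0,1] column normalization) and a nine-hidden-layer all-ReLU network
  trained with Nadam as the baseline.
* **Clinical evaluation**: RMSE/MAE/R/ME, `MAP = (SBP + 2·DBP)/3`, AAMI
  verdicts (|ME| ≤ 5, SD ≤ 8 mmHg), BHS A–D grading, the seven-class
  ESH/ESC hypertension classification with prevalence-weighted
  confusion summaries, and Bland–Altman limits of agreement
  (bias ± 1.96·SD).

A synthetic-waveform module generates paired PPG/ABP records with
analytic ground truth (beat onsets, five fiducials per beat, per-beat
SBP/DBP), so the whole pipeline runs and is tested without downloading
any waveform corpus. See the methods vignette
(`vignettes/bp-estimation-methods.Rmd`) for the model, parameter and
design details.

## Worked example

```r
library(ppgbp)

rec <- generate_record(record_spec(n_beats = 120, noise_sd = 0.02,
                                   drift_amplitude = 0.2,
                                   ppg_abp_lag_s = 0.1, seed = 42))
pulses <- process_record(rec$record)
attr(pulses, "lag")               # 12  <- the injected 0.1 s = 12.5 samples
nrow(pulses)                      # 112 of 120 beats survive the gates

tab <- build_feature_table(pulses)      # 112 rows x 154 features + targets
rr  <- rrelieff_scores(tab, "sbp", seed = 1)
k   <- choose_k(rr)                     # importance > 0.001
rank <- mrmr_rank(tab, "sbp", k = min(k, 20))
head(rank$features, 3)
#> "enh_stat_p10" "enh_sdppg_b_a" "enh_amp_inflection"

hp <- list(learning_rate = 0.2, max_depth = 4, subsample = 0.9,
           colsample_bytree = 0.9, lambda = 1, alpha = 1e-10,
           n_estimators = 150)
m <- train_xgboost(tab, "sbp", hp, features = rank$features,
                   folds = 5, seed = 1)
print(m)
#> bp_model (xgboost) for sbp: 20 features
#>   CV RMSE 3.035 mmHg, MAE 2.365 mmHg (5 folds)
```

The cross-validated RMSE of about 3 mmHg is the honest figure here (the
training-set residuals of a boosted ensemble are near zero and say
nothing). The evaluation layer works directly on numbers, published or
computed:

```r
classify_esh_esc(118, 78)      # Optimal
aami_check(0.020, 5.67)$pass   # TRUE  (|ME| <= 5, SD <= 8)
round(loa_limits(0.020, 5.67), 2)
#> -11.09 11.13                 # Bland-Altman limits from ME/SD
```

A thin command-line front end over the same functions lives in
`inst/cli/ppgbp` (subcommands `simulate`, `preprocess`, `features`,
`select`, `evaluate`).

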