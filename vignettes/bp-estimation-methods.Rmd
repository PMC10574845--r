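---
title: "Methods: cuff-less blood-pressure estimation from PPG morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cuff-less blood-pressure estimation from PPG morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgbp)
```

## The problem and the modeling approach

Continuous, cuff-less blood-pressure monitoring from a single
photoplethysmographic (PPG) sensor rests on the observation that the
shape of the optical pulse wave carries information about arterial
pressure: pulse amplitude tracks pulse pressure, the timing and
prominence of the dicrotic landmarks reflect vascular tone, and the
second-derivative (SDPPG) waves encode arterial stiffness. `ppgbp`
implements the full regression pipeline from paired PPG/arterial blood
pressure (ABP) waveforms to clinically evaluated systolic (SBP) and
diastolic (DBP) estimators:

1. **Conditioning** — channel alignment, 0.5–10 Hz zero-phase band-pass
   denoising, Z-score standardization, 0.5 Hz high-pass baseline
   correction, foot-to-foot segmentation, quality and PPG/ABP
   shape-similarity gating, per-pulse labeling with the ABP extrema, and
   the physiologic range filter (80–180 mmHg SBP, 60–110 mmHg DBP,
   bounds inclusive).
2. **Enhancement** — a maximal overlap discrete wavelet transform
   (MODWT) multiresolution analysis of each pulse; dropping the finest
   detail level denoises without shifting landmarks (the MODWT is
   undecimated, hence shift invariant).
3. **Features** — a fixed, versioned registry of
   `r nrow(feature_registry())` morphology features (amplitudes, times,
   areas, log-positions, statistics, first/second derivatives with the
   SDPPG a–e waves, single-pulse DFT harmonics), computed on the raw and
   the enhanced pulse.
4. **Selection** — greedy mRMR ordering (mutual-information difference
   scheme) with the number of retained features fixed by the RReliefF
   importance threshold (scores strictly above 0.001 count).
5. **Models** — XGBoost under Gaussian-process Bayesian hyper-parameter
   search (7-fold search CV, 10-fold training CV, [0,1] min–max column
   normalization stored with the model), and an all-ReLU nine-layer
   feed-forward network trained with Nadam as the baseline.
6. **Evaluation** — RMSE/MAE/R/ME, mean arterial pressure
   `MAP = (SBP + 2 DBP)/3`, the AAMI verdict (|ME| ≤ 5, SD ≤ 8 mmHg,
   inclusive), BHS grading (A/B/C/D from the cumulative fractions of
   absolute errors within 5/10/15 mmHg, all three thresholds required),
   the seven-class ESH/ESC hypertension classification with one-vs-rest
   confusion summaries, and Bland–Altman limits of agreement
   (bias ± 1.96·SD).

## What the synthetic generator emulates — and what it does not

No waveform corpus ships with the package. `generate_record()` emits
paired 125 Hz PPG/ABP records with analytic ground truth so that every
stage is testable:

* A beat is a train of 2–3 positive Gaussian bumps (systolic wave,
  diastolic wave, broad envelope). Beats are overlap-added with their
  tails, which produces smooth, physiological feet between beats. The
  ABP beat is a broadened, skewed copy with a linear diastolic runoff
  (so the pressure minimum falls at end-diastole) and an explicitly
  carved dicrotic notch, mapped affinely onto `[DBP, SBP]`.
* SBP/DBP vary beat to beat: a slow sinusoidal trend (defaults 15/8 mmHg
  over 40 beats, emulating baroreflex-scale variation) plus 2 mmHg
  per-beat jitter. PPG amplitude is coupled to pulse pressure and the
  diastolic wave to SBP/DBP, so regression targets are learnable from
  morphology.
* Nuisances: white Gaussian noise on both channels, a single sinusoidal
  baseline drift on the PPG, and an optional deliberate PPG delay
  bounded by one beat period to exercise the aligner.
* Ground truth (onsets, five landmarks per beat, per-beat SBP/DBP) is
  read off the noiseless streams by exhaustive scan, never by the
  detection path under test.

Because the aligner defines "aligned" as the maximum of the normalized
cross-correlation between the channels, the generator measures the
residual morphological offset between its PPG and ABP shapes and removes
it before injecting any requested lag; a zero-lag record is therefore
exactly aligned under the aligner's own criterion, which is what makes
sample-exact lag recovery a meaningful test.

The generator does **not** attempt hemodynamic realism: no arrhythmias,
motion artifacts, reflected-wave physiology, sensor saturation, or
inter-subject morphology variation. Passing tests demonstrate the
correctness of the algorithms under controlled conditions, not clinical
performance on ICU data; headline errors of the original study
(multi-million-pulse corpus) are out of desk-scale reach by design.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| Denoising band | 0.5–10 | Hz | standard PPG band; zero-phase 4th-order Butterworth preserves fiducial timing |
| Baseline cutoff | 0.5 | Hz | removes respiratory/motion drift, keeps the pulse fundamental (≥ 0.4 Hz at 25 bpm) |
| Beat duration bounds | 0.25–2.4 | s | 25–240 bpm plausibility |
| Quality template correlation | 0.9 | – | the gating statistic is not published; configurable |
| PPG/ABP shape similarity | 0.8 | – | same status; Pearson correlation of resampled shapes |
| MODWT wavelet / depth | `sym4`, J = 4 | – | symmlets preserve waveform symmetry; at 125 Hz, D1 ≈ 31–62 Hz is noise, D2..S4 span the pulse band |
| Enhancement | drop D1 | – | denoise without landmark shift |
| mRMR bins / scheme | 16, MID | – | reproducible, oracle-testable; scheme configurable |
| RReliefF | 10 neighbors, σ = 5, ≤ 5000 iterations | – | literature-standard parameterization |
| Importance threshold | > 0.001 (strict) | – | features at or below are treated as uncorrelated noise |
| Search CV / training CV | 7-fold / 10-fold | – | study protocol |
| NN | 9 hidden layers 1024…64, ReLU, Nadam, batch 4096, 150 epochs, val split 0.2 | – | reference architecture; `scale = "small"` (64/32, 20 epochs, lr 0.01) is the desk profile |

## Numerical and design choices

* **Coordinates.** Sample indices are 1-based and a pulse occupies the
  inclusive range `[start, end]` — the idiomatic R convention. The
  log-position features use the zero-based index through `ln(1 + i)`,
  so they are invariant to that representation choice.
* **Alignment.** Cardiac signals are quasi-periodic, so raw
  cross-correlation is ambiguous at multiples of the beat period. The
  aligner first matches the per-beat peak-amplitude sequences of the two
  channels (beat-to-beat variation is a fingerprint; both channels are
  detrended with a running mean of two beat periods first), then refines
  by raw correlation within half a beat period. The search bound
  defaults to ±2 s.
* **Labels.** SBP/DBP are the per-pulse ABP extrema. The labeler skips
  the first 3 samples of each segment (`onset_guard`) so onset-detection
  jitter cannot pull the previous beat's end-diastolic minimum into the
  current beat's DBP.
* **Fiducial cascade.** No distinct dicrotic notch → use the
  second-derivative maximum after the peak; no diastolic peak → fall
  back to the inflection point; a systolic peak past 60 % of the pulse
  violates systole-precedes-diastole and excludes the pulse. SDPPG
  waves that cannot be located fall back to the notch index so feature
  vectors stay finite.
* **ESH/ESC overlaps.** The printed class rules overlap (SBP 150 /
  DBP 85 is both Grade 1 by the systolic arm and isolated systolic
  hypertension). The classifier cascades: ISH first
  (SBP ≥ 140 and DBP < 90), then Grades 3/2/1 as the maximum of the two
  component grades, then High Normal / Normal / Optimal. This yields a
  partition, as a confusion matrix requires.
* **Prevalence weighting.** Class-table averages are
  `Σ metric·prevalence/100` with the printed prevalences and no
  renormalization; classes absent from truth and prediction are excluded
  as undefined.
* **RReliefF duplicates.** Exact duplicate rows are collapsed before the
  neighbor search: a duplicate carries no contrast information, and the
  estimate becomes invariant to row duplication.
* **MODWT boundaries.** Periodic for the exact energy/reconstruction
  identities; reflection (mirror extension) by default in
  `enhance_pulse()` to limit edge artifacts on short pulses.
* **GP search.** Latin-hypercube burn-in, RBF kernel on the unit cube
  with lengthscale/noise picked per iteration from a small
  marginal-likelihood grid, expected-improvement acquisition over 500
  random candidates per step; log scaling for λ, α, the learning rate
  and the tree count. Acquisition and trial count (default 50) are not
  published; expected improvement is standard GP-BO practice.
* **Desk-scale search space.** The reference spaces allow up to
  5100–6000 trees at depth 15–20, sized for a 9·10⁶-row corpus. The
  `"desk"` profile (depth ≤ 8, ≤ 300 trees) is the package's default
  for its own benchmarks, which use 50 000 synthetic rows with a 3 mmHg
  noise floor (`bp_recovery_benchmark()`: mRMR to 10 features, 20
  search trials on an 8 000-row subsample with 5-fold CV, final 5-fold
  training, 20 % held-out test). On those conditions the test RMSE
  approaches the noise floor from above.
* **NN output.** All layers ReLU, including the output; the output bias
  is initialized at the training-target mean so the output unit starts
  active. No early stopping; epochs are fixed.
* **Splitting.** Observation-level by default, mirroring the study
  protocol. This leaks intra-subject correlation when several pulses
  come from one subject; training on distinct `subject_id`s and
  holding out whole subjects is the leakage-safe alternative, supported
  by the `subject_id` column carried through the tables.

## Known limitations

* The 195-feature registry of the original study is not recoverable from
  its description; the package's registry covers every named family and
  is documented (`feature_registry()`), but is not a bit-exact clone.
* Published DBP and MAP limits of agreement are not arithmetically
  consistent with the printed error tables (1.96·3.95 = 7.742, not
  7.75; the MAP lower bound appears to be a sign typo); only the SBP
  limits are used as a numerical check.
* The WFDB reader/writer supports the single-segment format-16 subset
  used by paired PLETH/ABP records, not the full WFDB specification.
* Full-architecture NN training (nine layers, 150 epochs) is supported
  but sized for GPU-scale corpora; desk use goes through
  `nn_config(scale = "small")`.
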