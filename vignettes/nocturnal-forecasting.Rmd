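---
title: "Methods: personalized next-day headache forecasting from nocturnal wearable data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personalized next-day headache forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and of the design
choices that were genuinely open. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## Data model

The unit of raw data is the **minute record**: a 1-minute aggregate of
electrodermal activity (EDA, µS), pulse rate (bpm), pulse-rate variability
(PRV, ms), respiratory rate (breaths/min) and wrist temperature (°C), plus a
state channel (`asleep`, `awake_in_bed`, `out_of_bed`) and an `observed`
flag. A **night** is the ordered minute records of one sleep period; it is
identified with the morning it ends on, and its outcome is that morning's
diary label (`none`, `non_migraine`, `migraine`). This join convention —
night *n* carries the label of the day the participant wakes into — is not
dictated by the data format, so it is pinned by tests rather than inferred:
predictions are meant to be available on awakening, about the day that is
just starting.

## Featurization

Out-of-bed minutes are excluded before modeling (physiology while up and
moving mostly reflects physical activity). The remaining minutes are cut
into consecutive, non-overlapping 5-minute windows anchored at the first
retained minute; gaps left by excluded or missing minutes close up, because
the windows are defined over *retained* minutes. Per window and signal we
take median, min, max and sample (n−1) SD — extremes and dispersion carry
the autonomic reactivity information that averages alone miss. The four
night-level sleep metrics (time in bed, asleep, awake in bed, out of bed)
repeat as constants on every row of their night, giving 9 signals × 4
statistics = 36 features.

Numerical edge rules, each pinned by a test:

* a trailing window of 3–4 minutes is kept, 1–2 minutes is dropped (an SD
  over fewer than 3 points is too unstable to be a feature);
* a window with fewer than 3 usable minutes for a signal yields `NA` stats,
  left to imputation;
* a night with fewer than 5 retained minutes yields no rows.

## Missingness

`missingness_association()` fits a mixed-effects logistic regression of the
per-minute missingness indicator on the night's label with a participant
random intercept (estimated on the aggregated binomial form, which has the
identical likelihood and is much faster), and reads a non-significant
likelihood-ratio test as "MCAR-consistent". `impute_mice()` then fills
missing interval cells with chained equations and predictive mean matching
(5 donors), run **independently within each (participant, night) stratum**
and never using the outcome column as a predictor — imputation cannot move
information across nights or from labels into features. Defaults are 5
imputations × 10 iterations; the completed tables are averaged into one
analysis table. That averaging is a documented simplification: the
downstream cross-validation consumes a single table, and no pooled
inference across imputations is attempted. Whether one should impute raw
minutes or derived features is not determined by the problem; imputing the
interval features (the analysis units) was chosen and is pinned by tests.
The chained-equations engine is implemented in the package itself.

## Group-level comparison

`fit_group_lmm()` compares each nightly metric (three sleep durations plus
five nightly signal medians) across the three next-day categories with a
linear mixed model: fixed label effect, participant random intercept, ML
fit, 2-df likelihood-ratio test. "Corrected for repeated measures" is read
as two things: the random intercept inside the model, and a Holm correction
across the eight metrics. Holm was chosen over Bonferroni for uniformly
more power with no independence assumptions, and over FDR because the
family is small and confirmatory. With a single participant the random
intercept is dropped and the fit degenerates (correctly) to fixed effects.

## The nested cross-validation framework

For one participant and one outcome:

1. **Eligibility.** At least 2 positive and 2 negative nights — the minimum
   for every outer training fold to retain one night of each class for
   inner pairing. Ineligible (participant, outcome) pairs are excluded with
   a logged reason.
2. **Outer loop (L1NO).** Each night is held out once, in full.
3. **Inner loop (L2NO).** Within the training nights, every (positive,
   negative) night pair is a validation fold. A hyperparameter setting is
   scored by the fraction of pairs whose positive night gets the higher
   *nightly* probability (ties ½) — the natural statistic for
   one-positive/one-negative folds, since each pair contributes exactly one
   concordance comparison. When the pair product exceeds `pair_cap`
   (default 200), pairs are subsampled without replacement under a derived
   seed.
4. **Refit and score.** The winning setting (ties broken toward the less
   complex setting; each grid is ordered simplest-first) is refit on all
   training nights and the held-out night is scored.
5. **Aggregation.** A night's risk is the arithmetic mean of its interval
   probabilities; metrics (AUROC by midrank Mann–Whitney, AUPRC by step
   integration) are computed on nightly predictions only. The best learner
   per participant is the max-AUROC one.

Leakage control is structural: the scaler, tuning decisions, and final fit
see only training-night rows (mutation tests perturb the held-out night and
assert bit-identical training artifacts); interval rows always share their
night's fold assignment; class imbalance (prevalences down to ~0.16) is
handled by inverse-prevalence row weights rather than resampling. No
probability calibration is applied — thresholds 0.25/0.50/0.75 operate on
raw model probabilities, and ties at a threshold are called positive so
0.50 behaves as the conventional default.

Hyperparameter grids are small and standard (`default_grids()`):
elastic net mixing {0.1, 0.5, 0.9} × penalty {0.001, 0.01, 0.1, 1}; random
forest 500 trees × feature fraction {√p/p, 1/3} × min leaf {1, 5, 20};
boosting rounds {100, 300} × depth {2, 3} × learning rate {0.05, 0.1}.
`compact_grids()` is the reduced version used by the demonstrations and the
calibration studies, where the property under test does not depend on grid
breadth.

Both tree learners are fit in xgboost — random forests as single-round
bagged parallel-tree ensembles (subsample 0.632, per-node feature
subsampling, unit learning rate) — so that **exact** TreeSHAP attributions
are available for every tree model. The min-leaf grid maps to
`min_child_weight` through the binary-logistic hessian bound (≤ 0.25 per
row), an approximate but monotone leaf-size control.

## Explanation

`shap_summary()` returns exact per-row, per-feature attributions on the
link (log-odds) scale: coefficient × centered value for the elastic net,
TreeSHAP for tree models; local accuracy (base + Σφ = model output) is
asserted to 1e-6 in tests. Attributions are computed on the per-participant
refit over all nights — an explanatory summary, deliberately not an
out-of-sample quantity. The 0.25 retention filter applies to the maximum
absolute per-row attribution by default (row-level points are what a
beeswarm shows); mean |φ| is available via `rank_by = "mean"`.

`fit_temporal_gam()` contrasts a signal's nocturnal dynamics across outcome
groups: per group, a cubic regression spline (basis dimension 20, GCV
smoothing) over minutes since sleep onset (first asleep minute), horizon
420 min, 1-minute grid. The model includes a **night-level random
intercept**; without it the pointwise bands treat ~10⁴ autocorrelated
minutes as independent and become meaninglessly narrow — with it, the
band reflects night-to-night variation and overlaps between groups under
the null. Fits are per participant group in spirit (the packaged studies
fit per cohort; with one participant's nights the same call applies).

## The simulator

`simulate_cohort()` is first-class, tested code, and defines the study
conditions used everywhere: 10 participants × 36 nights by default (the
~315-night scale of a month-long 10-participant study), migraine /
non-migraine day probabilities 0.25 / 0.17, nightly time in bed
~N(505, 55²) min (median ≈ 504), and per-signal baselines that put nightly
medians at ≈0.3 µS EDA (log-normal, right-skewed, IQR ≈ 0.1–1.0), ≈70 bpm
pulse rate, ≈27 ms PRV, ≈16.4 breaths/min, ≈34.5 °C. Each signal has
participant- and night-level random intercepts plus AR(1) minute noise
(lag-1 coefficient 0.7), labels are i.i.d. per night (nights are modeled
independently downstream), out-of-bed excursions are 1–3 random blocks of
2–10 min, and missingness is MCAR at a configurable rate. Per-participant
seeds derive from a documented stable hash of (seed, participant id).

Planted effects are knobs, not estimates: a Gaussian EDA bump (SD 35 min)
centred 135 min after sleep onset on pre-migraine nights (the centre of the
120–150 min window where pre-migraine EDA peaks are reported), a PRV step
of `early_drop` before / `late_rise` after a 150-min changepoint, and a
sleep-duration shift on pre-headache nights. The "strong amplitude" regime
used by the recovery studies — 1.5 µS bump, −60 min sleep, ∓5 ms PRV — was
chosen once to land best-learner AUROCs in the 0.7–0.9 range rather than at
ceiling, mirroring the regime where such models are reported to work.

What the simulator does **not** emulate: raw 64 Hz/4 Hz waveforms, sleep
stages (REM/NREM) and their PRV signature, EDA spikes/storms, serial
dependence of headache days, menstrual-cycle or medication covariates, and
device-specific artifacts. Passing tests therefore show that the pipeline
recovers the *kind* of signal it assumes, under realistic noise,
autocorrelation and missingness — not that real cohorts contain such
signal.

## Problem sizes of the packaged studies

The calibration studies fix their own scales (chosen as the smallest that
make their statistical statements stable):

* null control — 20 effect-free participants × 36 nights (short ~150-min
  nights: interval count per night is irrelevant to chance-level AUROC),
  compact grids, pair cap 6;
* signal recovery — 20 replicate planted-effect participants × 30
  medium-length (~240-min) nights, so the 135-min EDA bump sits inside
  every night;
* GAM localization — 2 participants × 40 full-length (~500-min) nights
  covering the 420-min horizon;
* family-wise error — 100 replicate null cohorts of 4 participants × 20
  nights;
* `scripts/acceptance.R` reruns the same studies at reduced replicate
  counts (8 null participants, 10 recovery seeds, 60 null cohorts).

## Known limitations

* Averaging multiply-imputed tables discards between-imputation variance.
* The leave-one-night-out outer loop is slightly pessimistic at small night
  counts (the held-out night's class is anti-correlated with the training
  prevalence); the null-control band in the tests brackets this.
* Interval independence within a night is a modeling convenience; interval
  probabilities are correlated, so the nightly CI (mean ± 1.96 SE over
  intervals) understates uncertainty.
* Tie-breaking among learners by AUROC alone, and the unstated multiplicity
  and tuning conventions, are this package's pinned choices, documented
  above rather than attributed to any external source.
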