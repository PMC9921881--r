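---
title: "Prefrontal valence recognition: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prefrontal valence recognition: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valeeg)
```

## The problem and the signal model

Emotional valence — how pleasant or unpleasant a felt emotion is — can be
read from spontaneous EEG, and for personalized (subject-dependent)
applications a minimal montage matters: a wearable headset with two
prefrontal electrodes is far easier to deploy than a full 10/20 cap.
`valeeg` implements a valence-recognition pipeline that uses only the Fp1
and Fp2 channels, motivated by frontal-asymmetry physiology: positive
affect is associated with relatively stronger left-frontal activity,
negative affect with right-frontal activity. The pipeline therefore
collapses the two channels into a single asymmetry series,

$$ y(t) = \mathrm{Fp1}(t) - \mathrm{Fp2}(t), $$

and computes every feature from $y(t)$. A symmetric (common-mode)
component cancels exactly in the difference; whatever class information
survives is lateralized activity.

Each trial is a fixed-length recording (the canonical geometry is 63 s at
128 Hz, of which the first 3 s are a pre-trial baseline) accompanied by a
continuous self-assessment rating of valence on a 1–9 scale. The baseline
is discarded outright; no baseline-statistic correction is applied.

## Band separation

The difference signal is decomposed into the classical EEG rhythms with
third-order Butterworth band-pass filters: delta 2–4 Hz, theta 4–8, alpha
8–12, beta 12–30, gamma 30–60, plus the three gamma subbands 30–40,
40–50 and 50–60 Hz ("fast gamma"). Design choices:

* **Zero-phase application.** Filters are applied forward and backward
  (`apply_bandpass`), the standard for offline EEG. The magnitude
  response is squared (effective 6th-order roll-off) and phase distortion
  is zero, which matters because the difference of two nearly identical
  channels is sensitive to relative phase shifts. The −3 dB points of the
  single-pass design sit exactly on the printed band edges
  (`filter_gain` verifies $|H| = 1/\sqrt2$ there).
* **Edge padding.** Each series is extended by odd reflection over
  `3 * n_coef` samples at both ends before filtering, suppressing edge
  transients on 20 s windows.
* **Realization.** Coefficients are applied as a direct transfer
  function. The narrowest design (delta, 2–4 Hz at 128 Hz sampling) was
  checked numerically: outputs remain finite and bounded in double
  precision, which is the contract; the factorization itself is not.
* **Delta starts at 2 Hz**, not 0.5 Hz — fidelity to the band table this
  pipeline standardizes on. Content below 2 Hz is simply never used.
* **Gamma's upper edge (60 Hz) sits at 15/16 of Nyquist** for 128 Hz
  data. There is no guard band, and recordings whose preprocessing
  already low-passed near 45 Hz will carry little fast-gamma content;
  the filters do not attempt to compensate.

Differencing is performed before filtering; the two operations commute
for linear filters, and differencing first halves the filtering work.

## Features

Five scalar features are computed per band and trial
(`extract_features`), all deliberately cheap:

* **Hjorth activity** — the population variance of $y$ (µV²).
* **Hjorth mobility** — $\sqrt{\mathrm{var}(\Delta y)/\mathrm{var}(y)}$,
  a dominant-frequency proxy; for a sampled sinusoid of frequency $f$ it
  equals $2\sin(\pi f/f_s)$ exactly.
* **Hjorth complexity** — mobility of $\Delta y$ over mobility of $y$;
  1 for a pure sinusoid, larger for broader spectra. The canonical
  square-root forms of mobility and complexity are implemented (the
  bare activity-ratio variants that sometimes appear in print are a
  typesetting artefact of the source literature).
* **Zero-crossings** — strict sign reversals, with zero samples
  inheriting the previous nonzero sign so grid-aligned sinusoids count
  deterministically.
* **Total spectral power (PSD)** — $\frac{1}{N^2}\sum_k |X_k|^2$, the
  mean power by Parseval's theorem. The mean is not removed first:
  band-passed signals are zero-mean by construction, so for pipeline
  signals PSD coincides with activity to within rounding. The pair is
  kept because practitioners expect both a time-domain and a
  frequency-domain power estimate, and their near-identity is itself a
  useful internal consistency check.

The derivative is the unscaled first difference. Scaling by $f_s$ would
multiply mobility by a constant (shared by every trial of a dataset) and
cancel entirely in complexity; since classification standardizes features
per training fold, the constant is irrelevant, and leaving it out keeps
cross-implementation numbers easy to compare. Variance is population
($1/N$) variance so that the Parseval identity with PSD is exact.

## Labels and trial selection

Ratings map to classes by fixed, configurable conventions
(`label_scheme`): binary *high* iff rating > 5; three-class *low* ≤ 3,
*high* ≥ 6, *neutral* between. The boundary conventions (strict or not)
are stated rather than inherited silently because continuous ratings
rarely hit them exactly, but degenerate synthetic inputs must behave
deterministically. Feature analyses use only the strongest emotions: the
8 lowest- and 8 highest-rated trials per subject (`select_strongest`),
labelled by selection side, which guarantees balanced folds. Ties break
by ascending trial index, the low side claims first, and the two sides
are always disjoint.

## Classification and evaluation

Everything is subject-dependent: one model per subject, leave-one-out
cross-validation over that subject's trials, and the cohort figure is
the unweighted mean of per-subject accuracies (`aggregate_cohort`,
reported to two decimals, rounding half away from zero — the convention
that reproduces published accuracy tables).

* **kNN** (`knn_predict`): k = 5, Euclidean distance. Distance ties
  break by lower training index; vote ties by the label of the nearest
  neighbour among the tied classes. These rules make the classifier a
  pure function of its inputs.
* **RBF-SVM**: cost and gamma are tuned per subject *inside* each LOOCV
  training fold by an inner 5-fold cross-validation, over
  $\log_2 C \in [-5, 15]$ and $\log_2\gamma \in [-15, 3]$ — conventional
  ranges; reported SVM numbers can shift a percent or two under other
  budgets. The default tuner is Bayesian (Latin-hypercube start,
  Gaussian-process surrogate, expected-improvement acquisition,
  30 evaluations); a deterministic grid tuner is available. Objective
  ties prefer smaller cost, then smaller gamma — the smoother model.
* **Leakage discipline.** The scaler (per-feature z-score) and the
  hyperparameter search see only the n−1 training trials of each fold.
  Tuning on all of a subject's trials would leak the held-out trial into
  model selection; the nested choice is the conservative reading of
  "tuned per subject" and is asserted by an exact test (perturbing a
  held-out trial changes nothing about its fold's scaler or tuned
  hyperparameters).

A null-model subtlety: under chance, LOOCV-kNN is *not* centred at 50%.
The held-out trial is missing from its own class, so with 20 + 20 trials
the five neighbours are a random 5-subset of 19 same-class and 20
other-class candidates, giving a per-fold success probability of
$\sum_{j\ge3}\binom{19}{j}\binom{20}{5-j}/\binom{39}{5} \approx 0.475$.
`loocv_chance_band` centres its binomial band there; a band centred at
0.5 would be mis-calibrated for exactly the evaluations this package
runs.

## The synthetic cohort generator

Gated recording archives cannot ship with a package, so `valeeg`
validates itself end-to-end on synthetic cohorts (`sim_spec`,
`generate_cohort`) that emulate the statistical structure the method
assumes — no more:

* Channels are sums of band-limited Gaussian noise (white noise through
  the package's own band filters, normalized to unit RMS and scaled).
  Default common-component amplitudes are 20/15/10/8/5 µV RMS for
  delta/theta/alpha/beta/gamma — the low-frequency-dominant shape of a
  resting scalp spectrum — plus 2 µV of white sensor noise per channel.
* Each band also carries an antisymmetric component (0.3 of the band
  amplitude) entering Fp1 with + and Fp2 with −. The class effect scales
  the effect band's antisymmetric amplitude by $\sqrt{r}$ on high-class
  trials, so the difference signal carries variance ratio $r$ exactly
  where the pipeline measures it. $r = 1$ is a true null.
* Ratings are truncated normals: low class mean 3, high class mean 7,
  SD 1. With these defaults the strongest-16 selection and the
  threshold-5 labels agree on essentially every synthetic trial, which
  keeps the band/timeslot analyses meaningful.
* Per-subject variability is a lognormal (sdlog 0.1) multiplicative
  factor on band amplitudes, drawn once per subject. Every subject has
  its own seeded generator, derived from the cohort seed by a stated
  splitting rule, so cohorts are reproducible and parallel-safe.

What the generator does **not** emulate: 1/f spectral slopes, eye-blink
and muscle artefacts, nonstationarity, volume-conduction structure, or
any realistic EEG morphology beyond band-limited power. Passing the
end-to-end tests therefore demonstrates that the pipeline recovers the
statistical effect it is designed to measure — not that any particular
accuracy will be attained on real recordings.

## Numerical choices and degenerate inputs

* Constant signals: activity 0, mobility/complexity `NA` (undefined, not
  an error); all-zero signals have 0 zero-crossings and 0 power.
* Zero-variance feature columns are left unscaled by the fold scaler
  (divisor 1) instead of producing NaNs.
* Quartiles in `boxplot_summary` use linear interpolation (R type 7)
  with whiskers at the data extremes — the five-number summary, not
  Tukey fences.
* EDF input is read with 16-bit quantization against the header's
  physical range; features on EDF round-trips match the source array to
  about one part in 10³ of the signal range, which is the format's
  resolution, not a pipeline tolerance.

## Problem sizes used in validation

The shipped tests exercise the full study geometry once — two cohorts of
32 subjects × 40 trials × 63 s at 128 Hz (one with a planted alpha
variance ratio of 2, one null) — and otherwise use scaled-down cohorts
(3–4 subjects, 10–20 trials of ~10 s) that preserve every structural
property while keeping the default test run fast. Monte-Carlo checks of
the planted ratio use 400 trials, where the variance-of-variance of a
4 Hz-wide band over 10 s windows puts the empirical ratio comfortably
within ±10% of the target.

## Known limitations

* Fast gamma at 128 Hz sampling has no anti-aliasing guard band, and
  upstream low-pass preprocessing of real data may depress that band.
* The SVM search budget trades accuracy stability for runtime;
  single-percent shifts across budgets are expected and documented
  rather than suppressed.
* Subject archives whose ratings fall entirely on one side of a
  threshold have no defined cross-validated accuracy; they are skipped
  with a warning and excluded from the cohort mean.
* The EDF writer exists for synthesis and round-trip validation; it
  writes one data record per file and is not a general-purpose EDF+
  annotator.
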