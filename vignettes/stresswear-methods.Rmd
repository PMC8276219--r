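---
title: "Methods: synthetic cohorts, signal conditioning and window classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cohorts, signal conditioning and window classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(stresswear)
```

## Problem

A wristband records four physiological modalities — blood-volume pulse (BVP,
64 Hz), electrodermal activity (EDA, 4 Hz), skin temperature (4 Hz) and
triaxial acceleration (32 Hz) — while a participant goes through a scripted
lab session that alternates rest phases with a mental and a physical
stressor. The task is to decide, for each fixed-length window of the
recording, whether the participant was under stress (binary) or under which
kind of stressor (ternary). This vignette documents the generative model
behind the synthetic cohorts, the signal-conditioning choices, and the
numerical conventions of the classifiers and the evaluation protocol.

## The session protocol

A full session lasts 6000 s: habituation 600 s, baseline 600 s, stressor A
1200 s, rest 600 s, baseline 600 s, stressor B 1200 s, rest 600 s, baseline
600 s. Which stressor comes first is randomized per subject. The "short"
profile scales every phase by 0.1 (600 s total) and is what the package's
own tests use; it keeps the phase structure while making repeated
end-to-end runs affordable.

```{r}
build_protocol(protocol_spec(short = TRUE, randomize_order = FALSE))
```

For binary labels, `mental_stress` and `physical_stress` map to `stress`
and everything else to `no_stress`; ternary labeling keeps the stressor
identity. The first class in each set (`no_stress`) is the tie-break winner
everywhere a tie can occur.

## Generative model of the synthetic cohorts

Each subject is a draw from a truncated-normal population over physiological
parameters; each channel is then simulated from those parameters:

* **BVP** — a pulse train: inter-beat intervals are drawn per beat from
  `N(60 / HR(phase), ibi_sd(phase))`, each beat placing a fixed biphasic
  template (systolic peak, undershoot, dicrotic bump, 0.6 s long), plus
  white noise. Heart rate rises under stress; beat-to-beat variability
  falls.
* **EDA** — a tonic level that ramps (first-order, time constant 30 s)
  toward an elevated target during stress, plus phasic skin-conductance
  responses: Poisson-distributed onsets (higher rate under stress) convolved
  with a bi-exponential kernel (rise about 1 s, decay about 4 s).
* **Temperature** — baseline plus a slow AR(1) drift (time constant 300 s)
  minus a smoothed drop during stress (peripheral vasoconstriction).
* **Acceleration** — per axis, gravity plus sensor noise; during the
  physical stressor, a 1–3 Hz oscillation (gross movement) plus movement
  jitter noise.

The key parameters, their defaults and the reasoning:

| parameter | default (mean ± sd) | unit | why |
|---|---|---|---|
| `baseline_hr` | 70 ± 8 | bpm | typical resting heart rate |
| `hr_reactivity_mental` | 15 ± 4 | bpm | moderate mental-stressor response |
| `hr_reactivity_physical` | 35 ± 6 | bpm | ergometer-style load |
| `ibi_sd_baseline` / `ibi_sd_stress` | 0.060 / 0.030 | s | variability drops under stress; capped at the baseline value per subject |
| `eda_tonic` | 4.0 ± 1.5 | µS | tonic skin conductance |
| `eda_tonic_rise_stress` | 3.0 ± 1.0 | µS | tonic rise under stress |
| `scr_rate_baseline` / `scr_rate_stress` | 2 / 8 | per min | nonspecific vs. stress-driven response rate |
| `temp_baseline` | 33.5 ± 0.7 | °C | distal skin temperature |
| `temp_drop_stress` | 0.4 ± 0.15 | °C | vasoconstriction effect |
| `motion_amplitude_physical` | 0.8 ± 0.2 | g | gross movement amplitude |
| `motion_jitter_physical` | 0.06 | g | movement-locked noise during physical load |
| `noise_*` | 0.05 / 0.02 / 0.01 / 0.02 | signal units | sensor noise per channel |

Two derived conditions exist. `null_reactivity()` zeroes every
phase-dependent effect (and ties the stress variability and SCR rate to
their baselines), producing recordings whose labels are unlearnable — the
calibration condition: any classifier scoring far from MCC 0 on it is
leaking information. `strong_reactivity()` pins the effects to the upper
end of lab-observed responses (heart-rate reactivity +25/+45 bpm, tonic
EDA rise 6 µS, 12 SCRs per minute, 0.8 °C temperature drop, 1.2 g motion)
— the condition under which a correct pipeline should recover the labels
well.

What the simulator does **not** emulate: motion artefacts bleeding into
BVP/EDA, sensor detachment, baseline drift between sessions, respiratory
coupling, and individual differences in SCR shape. It is a test harness
with known ground truth, not a physiological model; conclusions about
classifier rankings on real data do not follow from it.

Every random draw descends from one integer seed via `derive_seed()`
(a Lehmer-style mix that stays below 2^31), so cohorts, fits and splits are
bit-reproducible, and concurrent streams (subjects, channels, epochs) are
independent.

## Signal conditioning

`preprocess_recording()` applies, in order:

1. **Bandpass on BVP only** — order-3 Butterworth, 0.04–4 Hz, applied
   forward and backward for zero phase shift. The series is demeaned and
   padded by odd reflection before filtering, which removes the edge
   transient that a naive filter start-up would leave (a constant input maps
   to exactly zero). The other channels carry their information at or near
   DC (tonic EDA level, temperature level), so they are not filtered.
2. **Acceleration magnitude** — the three axes collapse to
   `sqrt(x^2 + y^2 + z^2)`, which is orientation-invariant.
3. **Rate harmonization** — all four working channels are linearly
   interpolated onto a common 4 Hz grid (the rate of the slowest sensors).
4. **Per-channel min–max scaling** to [0, 1] over the whole recording,
   which removes inter-subject offsets while preserving within-recording
   shape. A constant channel maps to zeros by convention. Per-window
   scaling is available (`scale_per_window`) but not the default: it
   discards the level information that distinguishes tonic EDA states.

## Windowing

Windows are half-open intervals `[t, t + w)` anchored at the session start
with stride `s`; a duration `T` admits `floor((T - w)/s) + 1` windows. A
window's label is the class covering the majority of it; the covered
fraction is its *purity*, and windows below the purity threshold (default
0.8) are dropped, so a window labeled `stress` really is at least 80%
stress by time.

## Classifier families and multivariate strategies

Four families, each applied either as one classifier per channel combined
by majority vote (*ensemble*) or as a single classifier on the concatenated
channels (*concatenate*):

* **`dtw_1nn`** — 1-nearest-neighbour under dynamic time warping with
  squared pointwise cost, step set {(1,0), (0,1), (1,1)} and a Sakoe–Chiba
  band of half-width `ceil(band_fraction * max(n, m))` (default fraction
  0.1). Distance ties break toward the lowest class index, then the lowest
  training index.
* **`interval_forest`** — per tree, `ceiling(sqrt(m))` random intervals
  (length ≥ 3) summarized by mean, standard deviation and least-squares
  slope; each feature set trains one randomForest tree; the forest predicts
  by majority vote over trees.
* **`spectral_forest`** — per tree, one random interval (length ≥ 16)
  represented by the magnitude spectrum of the mean-removed interval plus
  autocorrelations at lags 1–32.
* **`fcn`** — a fully convolutional network: three blocks of
  convolution → batch normalization → ReLU with widths (64, 128, 64) and
  kernel lengths (8, 5, 3), same padding, global average pooling and a
  softmax layer; trained with Adam (20 epochs, learning rate 1e-3, batch
  size 32) on cross-entropy. The implementation is plain R with BLAS-backed
  im2col convolutions — no deep-learning framework is required.

One deliberate deviation: under the concatenate strategy the FCN receives
the channels as parallel convolution input channels rather than as a
literally appended series, because literal appending creates artificial
boundaries that convolution kernels would straddle. Set the hyperparameter
`literal_concat = TRUE` to force literal appending. On single-channel data
both strategies are constructed to coincide exactly for every family
(shared derived seeds), which is one of the package's invariant tests.

## Evaluation

Datasets are split 80/20. The default is a uniform sample-wise split, but
**subject-wise splitting is recommended whenever windows overlap**: with
stride < window, adjacent windows share most of their samples, and a
sample-wise split then places near-duplicates on both sides — memorization
masquerades as skill. The package's own null-calibration test uses
subject-wise splits for exactly this reason.

The headline metric is the Matthews correlation coefficient (MCC), which
stays honest under class imbalance (the protocol yields roughly 60/40
no-stress/stress windows; a majority guesser gets accuracy 0.6 but MCC 0).
Degenerate confusion tables (a zero marginal) return MCC 0 by convention.
Accuracy is reported alongside. `grid_search()` sweeps windows × strides ×
classifier configurations, ranks by MCC, and `summarize_top_k()` reduces
each family × strategy group to the distribution of its k best
configurations — the tabular form behind a violin-style tuning plot.

The problem sizes used in the package's tests (8-subject short-profile
cohorts, windows of 15–60 s) are the package's own choices, sized so that
the full pipeline — including the FCN — runs in minutes on one CPU while
still exercising every code path at realistic signal-to-noise ratios.

## Limitations

Synthetic validation bounds correctness, not real-world performance.
Classifier rankings, optimal window sizes and attainable MCC on the
simulator need not transfer to human data; the evaluation module is
deliberately agnostic about where the cohort comes from, and
`read_recording()` / `read_cohort()` accept real exports in the documented
CSV dialect.
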