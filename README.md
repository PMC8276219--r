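# stresswear

Wearable stress detection from multichannel physiological time series.

A wristband records blood-volume pulse (BVP, 64 Hz), electrodermal activity
(EDA, 4 Hz), skin temperature (4 Hz) and triaxial acceleration (32 Hz)
while a participant goes through a scripted session alternating rest with a
mental and a physical stressor. `stresswear` implements the full analysis
pipeline for deciding, per fixed-length window, whether the participant was
under stress:

1. **Synthetic cohorts** — a generative simulator of the session protocol
   with known per-subject effect sizes (pulse-train BVP, tonic + phasic
   EDA, drifting temperature, movement-locked acceleration), so every
   downstream estimator can be validated against ground truth.
2. **Preprocessing** — zero-phase Butterworth bandpass (0.04–4 Hz) on BVP,
   acceleration magnitude, linear resampling of all channels to a common
   4 Hz grid, per-recording min–max scaling to [0, 1].
3. **Windowing** — half-open windows `[t, t + w)` on a stride grid,
   majority-class labels with a purity threshold (default 0.8), binary
   (stress / no stress) or ternary (mental / physical / none) label modes.
4. **Classifiers** — four families: DTW 1-nearest-neighbour (Sakoe–Chiba
   band), interval-statistics forest, spectral-interval forest, and a fully
   convolutional network (three conv–batchnorm–ReLU blocks, widths
   64/128/64, kernels 8/5/3, global average pooling), each usable as one
   classifier per channel combined by majority vote (**ensemble**) or as a
   single classifier on the concatenated channels (**concatenate**).
5. **Evaluation** — seeded 80/20 splits (sample- or subject-wise), Matthews
   correlation coefficient and accuracy, grid search over window × stride ×
   configuration, and top-k distribution summaries.

The methods vignette (`vignettes/stresswear-methods.Rmd`) documents the
generative model, every numerical convention (tie-breaks, degenerate-case
conventions, filter realization) and the limitations of synthetic
validation.

## Worked example

Simulate an eight-subject cohort with strong stress reactivity under the
short (600 s) session profile, preprocess it, cut 60 s windows at a 30 s
stride, and compare two classifier configurations on a held-out split:

```r
library(stresswear)

cfg <- strong_reactivity(cohort_config(n_subjects = 8, seed = 11,
                                       short = TRUE))
cohort <- preprocess_cohort(generate_cohort(cfg))
dataset <- build_dataset(cohort, window_s = 60, stride_s = 30)
dataset
#> <windowed_dataset> 120 samples (4 ch x 240 pts), window 60 s, stride 30 s
#>
#> no_stress    stress
#>        72        48

res <- evaluate_config(cohort, classifier_spec("interval_forest",
                                               "concatenate", seed = 7),
                       window_s = 60, stride_s = 30,
                       split = list(fraction = 0.8, mode = "sample",
                                    seed = 1),
                       dataset = dataset)
c(mcc = res$mcc, accuracy = res$accuracy)
#>      mcc accuracy
#>        1        1

res$confusion
#>            predicted
#> true        no_stress stress
#>   no_stress        15      0
#>   stress            0      9

spc <- evaluate_config(cohort, classifier_spec("spectral_forest",
                                               "ensemble", seed = 7),
                       window_s = 60, stride_s = 30,
                       split = list(fraction = 0.8, mode = "sample",
                                    seed = 1),
                       dataset = dataset)
c(mcc = spc$mcc, accuracy = spc$accuracy)
#>       mcc  accuracy
#> 0.3892495 0.7083333
```

The contrast is the point: on this cohort the concatenation strategy lets
the forest exploit the informative channels directly, while per-channel
ensembling dilutes them behind a majority vote — and accuracy (0.71) looks
far friendlier than the Matthews correlation (0.39), which is why MCC is
the headline metric under class imbalance.

On a cohort with all reactivity parameters set to zero
(`null_reactivity()`), the same pipeline scores at chance — the package's
test suite asserts this calibration property, along with oracle equivalence
of the DTW and MCC implementations and the qualitative finding that larger
windows (15 → 60 s) give non-decreasing top-3 median MCC.

Recordings can also be written to and read from disk in a plain CSV dialect
(`write_cohort()` / `read_cohort()`), so real wristband exports can enter
the pipeline at the same point as simulated ones.

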