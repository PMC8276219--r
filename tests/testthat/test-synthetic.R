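test_that("subject parameter draws are reproducible and respect moments", {
  cfg <- cohort_config(n_subjects = 4, seed = 42)
  expect_identical(draw_subject_params(cfg, 2), draw_subject_params(cfg, 2))
  expect_false(identical(draw_subject_params(cfg, 1),
                         draw_subject_params(cfg, 2)))

  # sd = 0 collapses every draw onto the population mean
  pop0 <- cfg$population
  pop0[, "sd"] <- 0
  cfg0 <- cohort_config(seed = 1, population = pop0)
  p <- draw_subject_params(cfg0, 3)
  expect_equal(p$baseline_hr, unname(pop0["baseline_hr", "mean"]))
  expect_equal(p$eda_tonic, unname(pop0["eda_tonic", "mean"]))

  # Monte-Carlo: 1000 draws of baseline_hr agree with the configured mean
  hrs <- vapply(1:1000, function(i) {
    draw_subject_params(cohort_config(seed = 5), i)$baseline_hr
  }, numeric(1))
  mu <- cfg$population["baseline_hr", "mean"]
  se <- cfg$population["baseline_hr", "sd"] / sqrt(1000)
  expect_lt(abs(mean(hrs) - mu), 3 * se)
  # stress never increases beat-to-beat variability
  expect_true(all(vapply(1:50, function(i) {
    q <- draw_subject_params(cohort_config(seed = 9), i)
    q$ibi_sd_stress <= q$ibi_sd_baseline
  }, logical(1))))
})

test_that("protocol annotation matches the session plan", {
  ann <- build_protocol(protocol_spec(randomize_order = FALSE))
  expect_equal(annotation_duration(ann), 6000)
  expect_equal(ann$phase,
               c("habituation", "baseline", "mental_stress", "rest",
                 "baseline", "physical_stress", "rest", "baseline"))
  expect_equal(ann$end - ann$start,
               c(600, 600, 1200, 600, 600, 1200, 600, 600))
  # contiguity is enforced by the constructor; first start at 0
  expect_equal(ann$start[1], 0)

  short <- build_protocol(protocol_spec(short = TRUE, randomize_order = FALSE))
  expect_equal(annotation_duration(short), 600)

  firsts <- vapply(1:200, function(s) {
    a <- build_protocol(protocol_spec(randomize_order = TRUE, seed = s))
    grep("stress", a$phase, value = TRUE)[1]
  }, character(1))
  expect_setequal(unique(firsts), c("mental_stress", "physical_stress"))
})

test_that("channel synthesis encodes the configured stress effects", {
  ann <- build_protocol(protocol_spec(short = TRUE, randomize_order = FALSE))
  cfg <- cohort_config(seed = 3, short = TRUE)
  params <- draw_subject_params(cfg, 1)
  params$hr_reactivity_physical <- 35
  params$scr_rate_baseline <- 2
  params$scr_rate_stress <- 10
  rec <- synthesize_channels(params, ann, seed = 21)
  expect_length(rec$channels, 6)

  # beat rate detected from the generated pulse signal itself:
  # local maxima of the 64 Hz BVP above half the pulse height
  beats_per_min <- function(lo, hi) {
    v <- rec$channels$bvp$values
    i0 <- floor(lo * 64) + 1; i1 <- floor(hi * 64)
    seg <- v[i0:i1]
    pk <- which(diff(sign(diff(seg))) == -2) + 1
    pk <- pk[seg[pk] > 0.5]
    # collapse maxima closer than 300 ms (one beat)
    pk <- pk[c(TRUE, diff(pk) > 0.3 * 64)]
    length(pk) / (hi - lo) * 60
  }
  bpm_base <- beats_per_min(ann$start[2], ann$end[2])     # baseline
  bpm_phys <- beats_per_min(ann$start[6], ann$end[6])     # physical stress
  expect_gt(bpm_phys, bpm_base + 15)

  # SCR onsets from the simulator's own event log
  ev <- rec$ground_truth$scr_events
  in_phase <- function(i) sum(ev >= ann$start[i] & ev < ann$end[i]) /
    (ann$end[i] - ann$start[i])
  stress_rate <- mean(c(in_phase(3), in_phase(6)))
  base_rate <- mean(c(in_phase(2), in_phase(5), in_phase(8)))
  expect_gt(stress_rate, base_rate)
})

test_that("zero reactivity and zero noise yield a flat heart rate", {
  ann <- build_protocol(protocol_spec(short = TRUE, randomize_order = FALSE))
  pop <- cohort_config()$population
  pop[, "sd"] <- 0
  cfg <- null_reactivity(cohort_config(population = pop, seed = 1))
  params <- draw_subject_params(cfg, 1)
  params$noise_bvp <- 0
  params$ibi_sd_baseline <- params$ibi_sd_stress <- 0
  rec <- synthesize_channels(params, ann, seed = 2)
  hr <- rec$ground_truth$phase_hr
  expect_equal(length(unique(hr$hr)), 1)
  # constant IBI: realized beat intervals identical across phases
  ibis <- diff(rec$ground_truth$beat_times)
  expect_lt(max(ibis) - min(ibis), 1e-9)
})

test_that("cohort generation is deterministic and validated", {
  cfg <- cohort_config(n_subjects = 8, seed = 31, short = TRUE)
  coh <- generate_cohort(cfg)
  expect_length(coh, 8)
  expect_true(all(vapply(coh, function(r) length(r$channels) == 6L,
                         logical(1))))
  coh2 <- generate_cohort(cfg)
  expect_identical(coh[[5]]$channels$bvp$values, coh2[[5]]$channels$bvp$values)
  coh3 <- generate_cohort(cohort_config(n_subjects = 8, seed = 32,
                                        short = TRUE))
  expect_false(identical(coh[[1]]$channels$bvp$values,
                         coh3[[1]]$channels$bvp$values))
  # every recording passed constructor validation (class is proof), and the
  # ground-truth sidecar is present for oracle checks downstream
  expect_true(all(vapply(coh, function(r) !is.null(r$ground_truth),
                         logical(1))))
})
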