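# Cohort simulator: pulse-train BVP, tonic+phasic EDA, drifting temperature
# and motion channels under the lab stress-induction protocol, with known
# per-subject effect sizes so downstream estimators can be checked against
# ground truth.

# -- seeded RNG plumbing -------------------------------------------------

#' Derive an independent stream seed from a master seed
#'
#' Lehmer-style integer mix of `(seed, k)`; the result always lies in
#' `[0, 2^31 - 1]`, so it is safe to pass to [set.seed()] anywhere. Used
#' throughout the package to give each subject, channel and split its own
#' reproducible random stream.
#'
#' @param seed Master integer seed.
#' @param k Stream index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, k) {
  s <- (abs(as.double(seed)) %% 2147483646) + 1
  for (i in seq_len(2)) s <- (s * 48271 + as.double(k) * 7919) %% 2147483647
  as.integer(s)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' seeded computations do not disturb surrounding randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  tries <- 0L
  while (length(bad) && tries < 1000L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
    tries <- tries + 1L
  }
  if (length(bad)) x[bad] <- pmin(pmax(x[bad], lower), upper)
  x
}

# -- protocol ------------------------------------------------------------

#' Specification of the stress-induction session
#'
#' The session runs habituation (10 min) and baseline (10 min), then a 20-min
#' stress-induction block, a 20-min recovery (10 min rest + 10 min baseline),
#' the second 20-min stress block, and a final 20-min recovery. One block
#' holds mental stressors, the other physical ones; their order is randomized
#' per subject to balance carry-over effects.
#'
#' @param short Scale all phase durations by 1/10 (desk-scale profile).
#' @param randomize_order Randomize which stressor block comes first.
#' @param stressor_order Order used when `randomize_order` is `FALSE`.
#' @param seed Integer seed governing the order draw.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(short = FALSE, randomize_order = TRUE,
                          stressor_order = c("mental", "physical"),
                          seed = 1L) {
  stopifnot(setequal(stressor_order, c("mental", "physical")))
  scale <- if (short) 0.1 else 1
  durations <- c(habituation = 600, baseline = 600, stress = 1200,
                 rest = 600) * scale
  structure(list(durations = durations, randomize_order = randomize_order,
                 stressor_order = stressor_order, seed = as.integer(seed)),
            class = "protocol_spec")
}

#' Build the phase annotation for one session
#'
#' @param spec A [protocol_spec()].
#' @return A [phase_annotation()] covering the full session contiguously, with
#'   exactly one mental and one physical stress block.
#' @export
build_protocol <- function(spec = protocol_spec()) {
  stopifnot(inherits(spec, "protocol_spec"))
  ord <- spec$stressor_order
  if (spec$randomize_order) {
    ord <- with_local_seed(derive_seed(spec$seed, 1L),
                           sample(c("mental", "physical")))
  }
  d <- spec$durations
  phases <- c("habituation", "baseline", paste0(ord[1], "_stress"),
              "rest", "baseline", paste0(ord[2], "_stress"),
              "rest", "baseline")
  durs <- unname(d[c("habituation", "baseline", "stress", "rest",
                     "baseline", "stress", "rest", "baseline")])
  ends <- cumsum(durs)
  phase_annotation(c(0, head(ends, -1)), ends, phases)
}

# -- subject and cohort configuration ------------------------------------

# population table: mean, sd and truncation bounds per subject parameter;
# magnitudes are standard psychophysiology (heart rate up and beat-to-beat
# variability down under stress, tonic skin conductance and SCR rate up,
# peripheral temperature slightly down, gross motion only under physical load)
default_population <- function() {
  p <- rbind(
    baseline_hr                = c(70,   8,    45,   100),
    hr_reactivity_mental       = c(15,   4,    0,    60),
    hr_reactivity_physical     = c(35,   6,    0,    80),
    ibi_sd_baseline            = c(0.060, 0.015, 0.005, 0.2),
    ibi_sd_stress              = c(0.030, 0.010, 0.001, 0.2),
    eda_tonic                  = c(4.0,  1.5,  0.5,  20),
    eda_tonic_rise_stress      = c(3.0,  1.0,  0,    15),
    scr_rate_baseline          = c(2.0,  1.0,  0,    20),
    scr_rate_stress            = c(8.0,  2.0,  0,    30),
    temp_baseline              = c(33.5, 0.7,  30,   36),
    temp_drop_stress           = c(0.4,  0.15, 0,    2),
    motion_amplitude_physical  = c(0.8,  0.2,  0,    3),
    motion_jitter_physical     = c(0.06, 0.006, 0,   1),
    noise_bvp                  = c(0.05, 0.005, 0,   1),
    noise_eda                  = c(0.02, 0.002, 0,   1),
    noise_temp                 = c(0.01, 0.001, 0,   1),
    noise_acc                  = c(0.02, 0.002, 0,   1)
  )
  colnames(p) <- c("mean", "sd", "lower", "upper")
  p
}

#' Configuration of a simulated cohort
#'
#' Defaults follow the study scale (32 subjects) and the wristband's public
#' channel rates (BVP 64 Hz, EDA 4 Hz, temperature 4 Hz, acceleration 32 Hz).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer master seed; all randomness derives from it.
#' @param short Use the 1/10-duration desk-scale protocol.
#' @param class_mode `"binary"` or `"ternary"` window labeling downstream.
#' @param rates Named sampling rates in Hz for `bvp`, `eda`, `temp`, `acc`.
#' @param population Matrix of per-parameter `mean`, `sd`, `lower`, `upper`
#'   rows as produced by the default; override entries to move the cohort.
#' @param randomize_order Randomize stressor-block order per subject.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 32, seed = 1L, short = FALSE,
                          class_mode = c("binary", "ternary"),
                          rates = c(bvp = 64, eda = 4, temp = 4, acc = 32),
                          population = default_population(),
                          randomize_order = TRUE) {
  class_mode <- match.arg(class_mode)
  stopifnot(n_subjects >= 1, all(rates > 0),
            all(c("bvp", "eda", "temp", "acc") %in% names(rates)),
            all(population[, "sd"] >= 0))
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 short = short, class_mode = class_mode, rates = rates,
                 population = population, randomize_order = randomize_order),
            class = "cohort_config")
}

#' Zero out every stress-effect parameter of a cohort configuration
#'
#' Produces a null cohort: heart-rate reactivities, tonic EDA rise, the
#' SCR-rate increase, the temperature drop and physical motion amplitude are
#' all forced to zero (stress IBI variability is tied to baseline), so the
#' phase labels carry no physiological signal.
#'
#' @param config A [cohort_config()].
#' @return The modified `cohort_config`.
#' @export
null_reactivity <- function(config) {
  p <- config$population
  zero <- c("hr_reactivity_mental", "hr_reactivity_physical",
            "eda_tonic_rise_stress", "temp_drop_stress",
            "motion_amplitude_physical", "motion_jitter_physical")
  p[zero, c("mean", "sd")] <- 0
  p["ibi_sd_stress", ] <- p["ibi_sd_baseline", ]
  p["scr_rate_stress", ] <- p["scr_rate_baseline", ]
  config$population <- p
  config
}

#' Set every stress-effect parameter to the upper end of lab-observed
#' responses
#'
#' Produces a strong-reactivity cohort: heart-rate reactivity +25 bpm
#' (mental) / +45 bpm (physical), tonic EDA rise 6 uS, SCR rate 12 per min
#' under stress, temperature drop 0.8 deg C and 1.2 g physical motion --
#' values at the top of the ranges reported for laboratory stressors, with
#' between-subject spread in proportion. Baseline physiology and noise are
#' untouched.
#'
#' @param config A [cohort_config()].
#' @return The modified `cohort_config`.
#' @export
strong_reactivity <- function(config) {
  p <- config$population
  p["hr_reactivity_mental", c("mean", "sd")] <- c(25, 5)
  p["hr_reactivity_physical", c("mean", "sd")] <- c(45, 7)
  p["ibi_sd_stress", c("mean", "sd")] <- c(0.020, 0.008)
  p["eda_tonic_rise_stress", c("mean", "sd")] <- c(6, 1.5)
  p["scr_rate_stress", c("mean", "sd")] <- c(12, 2.5)
  p["temp_drop_stress", c("mean", "sd")] <- c(0.8, 0.2)
  p["motion_amplitude_physical", c("mean", "sd")] <- c(1.2, 0.25)
  config$population <- p
  config
}

#' Draw the physiological parameters of one subject
#'
#' Truncated-normal draws from the cohort population table, reproducible from
#' `(config$seed, subject_index)`. Stress IBI variability is capped at the
#' baseline value (stress reduces heart-rate variability).
#'
#' @param config A [cohort_config()].
#' @param subject_index Integer subject index, 1-based.
#' @return Named list of subject parameters.
#' @export
draw_subject_params <- function(config, subject_index) {
  stopifnot(inherits(config, "cohort_config"), subject_index >= 1)
  p <- config$population
  draws <- with_local_seed(derive_seed(config$seed, 1000L + subject_index), {
    vapply(rownames(p), function(f) {
      rnorm_trunc(1, p[f, "mean"], p[f, "sd"], p[f, "lower"], p[f, "upper"])
    }, numeric(1))
  })
  draws["ibi_sd_stress"] <- min(draws["ibi_sd_stress"], draws["ibi_sd_baseline"])
  as.list(draws)
}

# -- channel synthesis ---------------------------------------------------

phase_lookup <- function(annotation, t) {
  i <- findInterval(t, annotation$start, rightmost.closed = FALSE)
  i[i < 1] <- 1L
  i[i > nrow(annotation)] <- nrow(annotation)
  annotation$phase[i]
}

is_stress_phase <- function(phase) phase %in% c("mental_stress", "physical_stress")

# first-order low-pass of x sampled at dt with time constant tau (seconds)
smooth_first_order <- function(x, dt, tau) {
  a <- exp(-dt / tau)
  as.numeric(stats::filter((1 - a) * x, a, method = "recursive"))
}

synth_bvp <- function(params, annotation, rate) {
  duration <- annotation_duration(annotation)
  n <- round(duration * rate)
  # beat-by-beat pulse train: IBI ~ N(60/HR(phase), ibi_sd(phase))
  beats <- numeric(0)
  t <- 0
  hr_of <- function(ph) {
    params$baseline_hr +
      if (ph == "mental_stress") params$hr_reactivity_mental
      else if (ph == "physical_stress") params$hr_reactivity_physical
      else 0
  }
  while (t < duration) {
    ph <- phase_lookup(annotation, t)
    sd_ibi <- if (is_stress_phase(ph)) params$ibi_sd_stress else params$ibi_sd_baseline
    ibi <- max(0.3, rnorm(1, 60 / hr_of(ph), sd_ibi))
    t <- t + ibi
    if (t < duration) beats <- c(beats, t)
  }
  # fixed biphasic pulse template: systolic upstroke, undershoot, dicrotic bump
  tt <- seq(0, 0.6, by = 1 / rate)
  template <- exp(-((tt - 0.10) / 0.035)^2) -
    0.35 * exp(-((tt - 0.22) / 0.06)^2) +
    0.25 * exp(-((tt - 0.34) / 0.05)^2)
  sig <- numeric(n + length(template))
  idx <- pmax(1L, round(beats * rate))
  for (i in idx) {
    j <- i:(i + length(template) - 1L)
    sig[j] <- sig[j] + template
  }
  sig <- sig[seq_len(n)] + rnorm(n, 0, params$noise_bvp)
  list(series = channel_series("bvp", sig, rate), beats = beats)
}

synth_eda <- function(params, annotation, rate) {
  duration <- annotation_duration(annotation)
  n <- round(duration * rate)
  dt <- 1 / rate
  t <- (seq_len(n) - 1) * dt
  stress <- as.numeric(is_stress_phase(phase_lookup(annotation, t)))
  tonic <- params$eda_tonic +
    params$eda_tonic_rise_stress * smooth_first_order(stress, dt, tau = 30)
  # phasic skin-conductance responses: Poisson onsets, bi-exponential kernel
  events <- numeric(0)
  for (i in seq_len(nrow(annotation))) {
    rate_min <- if (is_stress_phase(annotation$phase[i])) params$scr_rate_stress
                else params$scr_rate_baseline
    dur_i <- annotation$end[i] - annotation$start[i]
    k <- rpois(1, rate_min / 60 * dur_i)
    if (k > 0) events <- c(events, sort(annotation$start[i] + runif(k) * dur_i))
  }
  kt <- seq(0, 20, by = dt)
  kernel <- exp(-kt / 4) - exp(-kt / 1)       # rise ~1 s, decay ~4 s
  kernel <- kernel / max(kernel)
  sig <- numeric(n + length(kernel))
  if (length(events)) {
    amps <- runif(length(events), 0.2, 0.6)
    idx <- pmax(1L, round(events * rate))
    for (e in seq_along(events)) {
      j <- idx[e]:(idx[e] + length(kernel) - 1L)
      sig[j] <- sig[j] + amps[e] * kernel
    }
  }
  vals <- tonic + sig[seq_len(n)] + rnorm(n, 0, params$noise_eda)
  list(series = channel_series("eda", vals, rate), scr_events = events)
}

synth_temp <- function(params, annotation, rate) {
  duration <- annotation_duration(annotation)
  n <- round(duration * rate)
  dt <- 1 / rate
  t <- (seq_len(n) - 1) * dt
  stress <- as.numeric(is_stress_phase(phase_lookup(annotation, t)))
  phi <- exp(-dt / 300)                        # slow AR(1) drift, tau 5 min
  innov_sd <- 0.05 * sqrt(1 - phi^2)
  drift <- as.numeric(stats::filter(rnorm(n, 0, innov_sd), phi,
                                    method = "recursive"))
  vals <- params$temp_baseline + drift -
    params$temp_drop_stress * smooth_first_order(stress, dt, tau = 60) +
    rnorm(n, 0, params$noise_temp)
  channel_series("temp", vals, rate)
}

synth_acc <- function(params, annotation, rate) {
  duration <- annotation_duration(annotation)
  n <- round(duration * rate)
  dt <- 1 / rate
  t <- (seq_len(n) - 1) * dt
  physical <- as.numeric(phase_lookup(annotation, t) == "physical_stress")
  gravity <- c(x = 0.02, y = -0.03, z = 0.98)
  lapply(c("x", "y", "z"), function(ax) {
    f <- runif(1, 1, 3)                        # gross movement, 1-3 Hz
    phi0 <- runif(1, 0, 2 * pi)
    amp <- params$motion_amplitude_physical * runif(1, 0.5, 1)
    vals <- gravity[[ax]] + rnorm(n, 0, params$noise_acc) +
      physical * (amp * sin(2 * pi * f * t + phi0) +
                    rnorm(n, 0, params$motion_jitter_physical))
    channel_series(paste0("acc_", ax), vals, rate)
  })
}

#' Synthesize the six raw channels of one subject session
#'
#' Generative model: BVP is a pulse train with phase-dependent heart rate and
#' inter-beat-interval variability, each beat a fixed biphasic template, plus
#' white noise; EDA is a phase-dependent tonic level (first-order ramp)
#' plus Poisson skin-conductance responses convolved with a bi-exponential
#' kernel; temperature is baseline plus a slow AR(1) drift minus a smoothed
#' drop during stress; the acceleration axes are low-amplitude noise with a
#' 1-3 Hz oscillation and movement jitter during physical stress. True beat times, SCR onsets and
#' per-phase heart rate are attached as ground truth.
#'
#' @param params Subject parameters from [draw_subject_params()].
#' @param annotation A [phase_annotation()].
#' @param rates Named rates in Hz (`bvp`, `eda`, `temp`, `acc`), all > 0.
#' @param seed Integer seed.
#' @param subject_id Identifier attached to the recording.
#' @return A [recording()] with 6 channels and a `ground_truth` list.
#' @export
synthesize_channels <- function(params, annotation,
                                rates = c(bvp = 64, eda = 4, temp = 4, acc = 32),
                                seed = 1L, subject_id = "S01") {
  if (any(rates <= 0)) stop("invalid_sampling_rate: rates must be > 0",
                            call. = FALSE)
  with_local_seed(seed, {
    bvp <- synth_bvp(params, annotation, rates[["bvp"]])
    eda <- synth_eda(params, annotation, rates[["eda"]])
    temp <- synth_temp(params, annotation, rates[["temp"]])
    acc <- synth_acc(params, annotation, rates[["acc"]])
    truth <- list(
      params = params,
      phase_hr = data.frame(
        phase = annotation$phase,
        hr = params$baseline_hr + ifelse(
          annotation$phase == "mental_stress", params$hr_reactivity_mental,
          ifelse(annotation$phase == "physical_stress",
                 params$hr_reactivity_physical, 0))),
      beat_times = bvp$beats,
      scr_events = eda$scr_events)
    recording(subject_id, c(list(bvp$series, eda$series, temp), acc),
              annotation, ground_truth = truth)
  })
}

#' Generate a labeled cohort of simulated recordings
#'
#' @param config A [cohort_config()].
#' @return List of `n_subjects` [recording()] objects, fully reproducible
#'   from `config$seed`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  lapply(seq_len(config$n_subjects), function(i) {
    params <- draw_subject_params(config, i)
    spec <- protocol_spec(short = config$short,
                          randomize_order = config$randomize_order,
                          seed = derive_seed(config$seed, 2000L + i))
    ann <- build_protocol(spec)
    synthesize_channels(params, ann, rates = config$rates,
                        seed = derive_seed(config$seed, 3000L + i),
                        subject_id = sprintf("S%02d", i))
  })
}
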