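# Signal conditioning: zero-phase bandpass on the pulse channel, collapse of
# the acceleration axes to a magnitude series, rate harmonization, and
# per-channel min-max scaling to [0, 1].

#' Preprocessing configuration
#'
#' @param bandpass_low,bandpass_high Passband edges in Hz for the pulse
#'   channel (defaults 0.04 and 4).
#' @param scale_to_unit Scale each working channel to [0, 1] per recording.
#' @param common_rate Target rate in Hz all working channels are resampled to.
#' @param scale_per_window If `TRUE`, scaling is deferred to window extraction
#'   and applied per window instead of per recording (sensitivity analysis).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(bandpass_low = 0.04, bandpass_high = 4,
                              scale_to_unit = TRUE, common_rate = 4,
                              scale_per_window = FALSE) {
  stopifnot(bandpass_low > 0, bandpass_low < bandpass_high, common_rate > 0)
  structure(list(bandpass_low = bandpass_low, bandpass_high = bandpass_high,
                 scale_to_unit = scale_to_unit, common_rate = common_rate,
                 scale_per_window = scale_per_window),
            class = "preprocess_config")
}

#' Zero-phase Butterworth bandpass filter
#'
#' Order-3 Butterworth applied forward and backward (no group delay). The
#' series is demeaned and odd-reflection padded before filtering so edge
#' transients stay out of the returned segment; the DC component is removed
#' exactly.
#'
#' @param series A [channel_series()] or numeric vector.
#' @param low,high Passband edges in Hz.
#' @param rate Sampling rate in Hz; taken from the series when it is a
#'   `channel_series`.
#' @return Filtered series of the same type, length and rate.
#' @export
bandpass_filter <- function(series, low = 0.04, high = 4, rate = NULL) {
  if (inherits(series, "channel_series")) {
    out <- series
    out$values <- bandpass_filter(series$values, low, high, series$sampling_rate)
    return(out)
  }
  stopifnot(is.numeric(series), length(series) > 1)
  if (is.null(rate)) stop("rate required for numeric input", call. = FALSE)
  if (rate <= 2 * high) {
    stop("rate_too_low: sampling rate ", rate,
         " Hz cannot represent a ", high, " Hz cutoff", call. = FALSE)
  }
  x <- series - mean(series)
  n <- length(x)
  pad <- min(n - 1L, ceiling(3 * rate / low))
  # odd reflection about the endpoints suppresses edge transients
  left <- 2 * x[1] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(left, x, right)
  bf <- signal::butter(3, c(low, high) / (rate / 2), type = "pass")
  y <- signal::filter(bf, xp)
  y <- rev(signal::filter(bf, rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Min-max scale a series to [0, 1]
#'
#' Minimum maps to 0 and maximum to 1; a constant series maps to all zeros
#' (stated convention). Idempotent, and exactly invariant to affine
#' transforms `a * x + b` with `a > 0`.
#'
#' @param series A [channel_series()] or numeric vector with finite values.
#' @return Scaled series of the same type.
#' @export
minmax_scale <- function(series) {
  if (inherits(series, "channel_series")) {
    out <- series
    out$values <- minmax_scale(series$values)
    return(out)
  }
  stopifnot(is.numeric(series), length(series) >= 1)
  if (!all(is.finite(series))) stop("nonfinite_values in minmax_scale",
                                    call. = FALSE)
  rng <- range(series)
  if (rng[1] == rng[2]) return(rep(0, length(series)))
  (series - rng[1]) / (rng[2] - rng[1])
}

#' Resample a channel onto a uniform grid by linear interpolation
#'
#' @param series A [channel_series()].
#' @param target_rate Target rate in Hz, > 0.
#' @return A `channel_series` at `target_rate`; duration preserved within one
#'   sample period.
#' @export
resample_channel <- function(series, target_rate) {
  stopifnot(inherits(series, "channel_series"))
  if (target_rate <= 0) stop("invalid_sampling_rate: target_rate must be > 0",
                             call. = FALSE)
  n <- length(series$values)
  if (n == 0) stop("empty_channel", call. = FALSE)
  span <- (n - 1) / series$sampling_rate
  m <- floor(span * target_rate) + 1L
  t_new <- (seq_len(m) - 1) / target_rate
  vals <- if (n == 1) rep(series$values, m) else {
    t_old <- (seq_len(n) - 1) / series$sampling_rate
    approx(t_old, series$values, xout = t_new)$y
  }
  channel_series(series$name, vals, target_rate, series$start_time)
}

#' Condition a raw recording into the four working channels
#'
#' Applies the bandpass to the pulse channel only, collapses the three
#' acceleration axes into one magnitude channel `acc` (sqrt(x^2+y^2+z^2)),
#' resamples the four working channels (`bvp`, `eda`, `temp`, `acc`) to the
#' common rate, and scales each to [0, 1] per channel per recording.
#' Deterministic.
#'
#' @param recording A raw six-channel [recording()].
#' @param config A [preprocess_config()].
#' @return A [recording()] with channels `bvp`, `eda`, `temp`, `acc` at
#'   `config$common_rate`, values in [0, 1] when scaling is on.
#' @export
preprocess_recording <- function(recording, config = preprocess_config()) {
  stopifnot(inherits(recording, "recording"),
            inherits(config, "preprocess_config"))
  ch <- recording$channels
  need <- c("bvp", "eda", "temp", "acc_x", "acc_y", "acc_z")
  if (!all(need %in% names(ch))) {
    stop("missing_channel: ", paste(setdiff(need, names(ch)), collapse = ", "),
         call. = FALSE)
  }
  bvp <- bandpass_filter(ch$bvp, config$bandpass_low, config$bandpass_high)
  ax <- ch$acc_x; ay <- ch$acc_y; az <- ch$acc_z
  stopifnot(ax$sampling_rate == ay$sampling_rate,
            ax$sampling_rate == az$sampling_rate)
  m <- min(length(ax$values), length(ay$values), length(az$values))
  acc <- channel_series(
    "acc",
    sqrt(ax$values[1:m]^2 + ay$values[1:m]^2 + az$values[1:m]^2),
    ax$sampling_rate, ax$start_time)
  working <- list(bvp = bvp, eda = ch$eda, temp = ch$temp, acc = acc)
  working <- lapply(working, resample_channel, target_rate = config$common_rate)
  if (config$scale_to_unit && !config$scale_per_window) {
    working <- lapply(working, minmax_scale)
  }
  recording(recording$subject_id, unname(working), recording$annotation,
            ground_truth = recording$ground_truth)
}

#' Preprocess every recording of a cohort
#'
#' @param cohort List of raw [recording()] objects.
#' @param config A [preprocess_config()].
#' @return List of preprocessed recordings.
#' @export
preprocess_cohort <- function(cohort, config = preprocess_config()) {
  lapply(cohort, preprocess_recording, config = config)
}
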