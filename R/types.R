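#' @useDynLib stresswear, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rpois approx fft acf sd quantile median cor predict
#' @importFrom utils head tail write.csv
NULL

# canonical channel and phase vocabularies -------------------------------

#' Channel names recognized by the pipeline
#'
#' Raw recordings carry six channels: blood-volume pulse (\code{bvp}),
#' electrodermal activity (\code{eda}), skin temperature (\code{temp}) and the
#' three acceleration axes. Preprocessing collapses the axes into a single
#' magnitude channel \code{acc}, so the working set downstream is
#' \code{c("bvp", "eda", "temp", "acc")}.
#'
#' @return Character vector of valid raw channel names.
#' @export
channel_names <- function() c("bvp", "eda", "temp", "acc_x", "acc_y", "acc_z")

#' @rdname channel_names
#' @export
working_channels <- function() c("bvp", "eda", "temp", "acc")

#' Phase labels of the stress-induction protocol
#'
#' @return Character vector of valid phase names.
#' @export
phase_names <- function() {
  c("habituation", "baseline", "mental_stress", "physical_stress", "rest")
}

#' Class sets for window labeling
#'
#' In binary mode the two stressor phases map to \code{stress} and all resting
#' phases to \code{no_stress}; ternary mode keeps mental and physical stress
#' apart. The first element is class index 0 and wins ties everywhere
#' (majority vote, nearest-neighbour ties).
#'
#' @param class_mode `"binary"` or `"ternary"`.
#' @return Character vector of class labels, in index order.
#' @export
class_set <- function(class_mode = c("binary", "ternary")) {
  class_mode <- match.arg(class_mode)
  if (class_mode == "binary") c("no_stress", "stress")
  else c("no_stress", "mental_stress", "physical_stress")
}

#' Map a protocol phase to its class label
#'
#' @param phase Character vector of phase names.
#' @inheritParams class_set
#' @return Factor with levels \code{class_set(class_mode)}.
#' @export
phase_to_class <- function(phase, class_mode = c("binary", "ternary")) {
  class_mode <- match.arg(class_mode)
  stopifnot(all(phase %in% phase_names()))
  lab <- if (class_mode == "binary") {
    ifelse(phase %in% c("mental_stress", "physical_stress"), "stress", "no_stress")
  } else {
    ifelse(phase %in% c("mental_stress", "physical_stress"), phase, "no_stress")
  }
  factor(lab, levels = class_set(class_mode))
}

# ChannelSeries ----------------------------------------------------------

#' A uniformly sampled physiological channel
#'
#' @param name Channel name, one of [channel_names()] or [working_channels()].
#' @param values Numeric vector of finite samples, length >= 1.
#' @param sampling_rate Sampling rate in Hz, > 0.
#' @param start_time Seconds since session start, >= 0.
#' @return An object of class `channel_series`.
#' @export
channel_series <- function(name, values, sampling_rate, start_time = 0) {
  if (!is.character(name) || length(name) != 1 ||
      !(name %in% union(channel_names(), working_channels()))) {
    stop("invalid_channel_name: ", name, call. = FALSE)
  }
  values <- as.numeric(values)
  if (length(values) < 1) stop("empty_channel: ", name, call. = FALSE)
  if (!all(is.finite(values))) stop("nonfinite_values: channel ", name, call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("invalid_sampling_rate: must be a single value > 0", call. = FALSE)
  }
  if (!is.finite(start_time) || start_time < 0) {
    stop("invalid_start_time: must be >= 0", call. = FALSE)
  }
  structure(
    list(name = name, values = values, sampling_rate = sampling_rate,
         start_time = start_time),
    class = "channel_series"
  )
}

#' Duration of a channel in seconds
#'
#' Spanned time from the first to one sample period past the last sample, so a
#' channel of n samples at rate r covers n / r seconds.
#'
#' @param x A `channel_series`.
#' @return Duration in seconds.
#' @export
channel_duration <- function(x) {
  stopifnot(inherits(x, "channel_series"))
  length(x$values) / x$sampling_rate
}

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf("<channel_series> %s: %d samples @ %g Hz (%.1f s)\n",
              x$name, length(x$values), x$sampling_rate, channel_duration(x)))
  invisible(x)
}

# PhaseAnnotation --------------------------------------------------------

#' Ordered phase intervals of a session
#'
#' Intervals must be sorted, non-overlapping and contiguous (each start equals
#' the previous end), starting at time 0.
#'
#' @param start,end Numeric vectors of interval bounds in seconds.
#' @param phase Character vector of phase names, see [phase_names()].
#' @return An object of class `phase_annotation`: a data frame with columns
#'   `start`, `end`, `phase`.
#' @export
phase_annotation <- function(start, end, phase) {
  if (length(start) != length(end) || length(start) != length(phase) ||
      length(start) < 1) {
    stop("malformed_annotation: start/end/phase lengths differ or empty",
         call. = FALSE)
  }
  o <- order(start)
  start <- as.numeric(start)[o]; end <- as.numeric(end)[o]
  phase <- as.character(phase)[o]
  if (!all(phase %in% phase_names())) {
    stop("unknown_phase: ", paste(setdiff(phase, phase_names()), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(start)) || any(!is.finite(end)) || any(start >= end)) {
    stop("malformed_annotation: need start < end for every interval",
         call. = FALSE)
  }
  if (start[1] != 0) stop("malformed_annotation: first interval must start at 0",
                          call. = FALSE)
  if (length(start) > 1) {
    gaps <- start[-1] - end[-length(end)]
    if (any(gaps > 1e-9)) stop("annotation_gap: intervals are not contiguous",
                               call. = FALSE)
    if (any(gaps < -1e-9)) stop("annotation_overlap: intervals overlap",
                                call. = FALSE)
  }
  structure(
    data.frame(start = start, end = end, phase = phase,
               stringsAsFactors = FALSE),
    class = c("phase_annotation", "data.frame")
  )
}

#' Total annotated duration in seconds
#' @param x A `phase_annotation`.
#' @export
annotation_duration <- function(x) {
  stopifnot(inherits(x, "phase_annotation"))
  x$end[nrow(x)]
}

# Recording --------------------------------------------------------------

#' A subject session: channels plus phase annotation
#'
#' @param subject_id Opaque subject identifier.
#' @param channels List of [channel_series()] objects with unique names.
#' @param annotation A [phase_annotation()].
#' @param ground_truth Optional list of simulator ground truth (per-phase true
#'   heart rate, skin-conductance-response event times); `NULL` for real data.
#' @return An object of class `recording`.
#' @export
recording <- function(subject_id, channels, annotation, ground_truth = NULL) {
  if (!length(channels)) stop("empty_channels: recording needs >= 1 channel",
                              call. = FALSE)
  stopifnot(all(vapply(channels, inherits, TRUE, "channel_series")),
            inherits(annotation, "phase_annotation"))
  nm <- vapply(channels, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate_channel: ", nm[duplicated(nm)][1],
                              call. = FALSE)
  names(channels) <- nm
  dur <- annotation_duration(annotation)
  spans <- vapply(channels, function(ch) ch$start_time + channel_duration(ch), 0)
  # one sample period of slack: the last window sample may fall on the boundary
  short <- spans < dur - 1 / min(vapply(channels, `[[`, 0, "sampling_rate"))
  if (any(short)) {
    stop("channel_too_short: ", paste(nm[short], collapse = ", "),
         " does not span the annotated session", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), channels = channels,
         annotation = annotation, ground_truth = ground_truth),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject %s: %d channels, %.0f s session\n",
              x$subject_id, length(x$channels),
              annotation_duration(x$annotation)))
  for (ch in x$channels) print(ch)
  invisible(x)
}
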