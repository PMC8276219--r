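# Segmentation of preprocessed recordings into fixed-length labeled windows.
# Window grid is anchored at session start with half-open intervals [t, t+w);
# a window's label is the class covering the majority of it, and windows
# whose majority-class coverage (purity) falls below a threshold are dropped.

#' Number of windows that fit a duration
#'
#' `floor((duration - window) / stride) + 1` when the duration admits at
#' least one window, otherwise 0.
#'
#' @param duration_s,window_s,stride_s Durations in seconds; window and
#'   stride must be > 0.
#' @return Integer window count.
#' @export
count_windows <- function(duration_s, window_s, stride_s) {
  if (window_s <= 0 || stride_s <= 0) {
    stop("invalid_windowing: window and stride must be > 0", call. = FALSE)
  }
  if (duration_s < window_s) return(0L)
  as.integer(floor((duration_s - window_s) / stride_s + 1e-9) + 1L)
}

#' Label a time interval from the phase annotation
#'
#' The label is the class (after class-mode mapping) covering the majority of
#' `[start_s, end_s)`; purity is that class's covered fraction. Returns
#' `NULL` when purity falls below the threshold (the window is dropped).
#' Class ties break toward the lowest class index.
#'
#' @param annotation A [phase_annotation()].
#' @param start_s,end_s Interval bounds in seconds, within the annotated span.
#' @param class_mode `"binary"` or `"ternary"`.
#' @param purity_threshold Minimum majority-class fraction to keep, in [0, 1].
#' @return `list(label = factor, purity = numeric)` or `NULL` if dropped.
#' @export
label_for_interval <- function(annotation, start_s, end_s,
                               class_mode = "binary", purity_threshold = 0.8) {
  stopifnot(inherits(annotation, "phase_annotation"), start_s < end_s)
  if (start_s < annotation$start[1] - 1e-9 ||
      end_s > annotation$end[nrow(annotation)] + 1e-9) {
    stop("interval_outside_annotation", call. = FALSE)
  }
  cover <- pmax(0, pmin(annotation$end, end_s) - pmax(annotation$start, start_s))
  cls <- phase_to_class(annotation$phase, class_mode)
  lev <- levels(cls)
  by_class <- vapply(lev, function(l) sum(cover[cls == l]), 0)
  win <- which.max(by_class)          # which.max takes the first (lowest) index
  purity <- by_class[win] / (end_s - start_s)
  if (purity < purity_threshold) return(NULL)
  list(label = factor(lev[win], levels = lev), purity = unname(purity))
}

#' Extract labeled windows from one preprocessed recording
#'
#' @param recording A preprocessed [recording()] (four working channels at a
#'   common rate).
#' @param window_s Window length in seconds.
#' @param stride_s Step between window starts in seconds.
#' @param purity_threshold Minimum majority-class fraction to retain a window.
#' @param class_mode `"binary"` or `"ternary"`.
#' @param scale_per_window Min-max scale each channel within each window.
#' @return List of window samples; each is a list with `values` (channel x
#'   time matrix, rows ordered `bvp`, `eda`, `temp`, `acc`), `label`,
#'   `purity`, `subject_id`, `window_start`.
#' @export
extract_windows <- function(recording, window_s, stride_s,
                            purity_threshold = 0.8, class_mode = "binary",
                            scale_per_window = FALSE) {
  stopifnot(inherits(recording, "recording"))
  nm <- working_channels()
  if (!all(nm %in% names(recording$channels))) {
    stop("missing_channel: expected preprocessed channels ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  rate <- recording$channels[[nm[1]]]$sampling_rate
  if (!all(vapply(recording$channels[nm], `[[`, 0, "sampling_rate") == rate)) {
    stop("rate_mismatch: working channels must share one rate", call. = FALSE)
  }
  duration <- min(annotation_duration(recording$annotation),
                  min(vapply(recording$channels[nm], channel_duration, 0)))
  if (duration < window_s) stop("window_longer_than_recording", call. = FALSE)
  n_win <- count_windows(duration, window_s, stride_s)
  wlen <- round(window_s * rate)
  samples <- vector("list", n_win)
  kept <- 0L
  for (k in seq_len(n_win)) {
    t0 <- (k - 1) * stride_s
    lab <- label_for_interval(recording$annotation, t0, t0 + window_s,
                              class_mode, purity_threshold)
    if (is.null(lab)) next
    i0 <- round(t0 * rate)
    vals <- t(vapply(nm, function(ch) {
      v <- recording$channels[[ch]]$values[(i0 + 1L):(i0 + wlen)]
      if (scale_per_window) minmax_scale(v) else v
    }, numeric(wlen)))
    rownames(vals) <- nm
    kept <- kept + 1L
    samples[[kept]] <- list(values = vals, label = lab$label,
                            purity = lab$purity,
                            subject_id = recording$subject_id,
                            window_start = t0)
  }
  samples[seq_len(kept)]
}

#' Build the learning corpus from a cohort
#'
#' Concatenates per-recording windows into a `windowed_dataset`: a 3-D array
#' of samples (sample x channel x time) with labels and subject provenance.
#'
#' @param cohort List of preprocessed [recording()] objects.
#' @param window_s,stride_s Window length and stride in seconds (default
#'   600 s windows, the optimum of the studied 150-1200 s range).
#' @param purity_threshold Minimum majority-class fraction to retain a window.
#' @param class_mode `"binary"` or `"ternary"`.
#' @param scale_per_window Min-max scale channels within each window.
#' @return An object of class `windowed_dataset` with elements `x` (array
#'   n x 4 x m), `labels` (factor), `subject` (character), `window_start`,
#'   `purity`, `window_s`, `stride_s`, `rate`, `channels`.
#' @export
build_dataset <- function(cohort, window_s = 600, stride_s = 300,
                          purity_threshold = 0.8, class_mode = "binary",
                          scale_per_window = FALSE) {
  stopifnot(length(cohort) >= 1)
  all_samples <- unlist(lapply(cohort, extract_windows, window_s = window_s,
                               stride_s = stride_s,
                               purity_threshold = purity_threshold,
                               class_mode = class_mode,
                               scale_per_window = scale_per_window),
                        recursive = FALSE)
  if (!length(all_samples)) {
    stop("empty_dataset: every window was dropped by the purity filter",
         call. = FALSE)
  }
  rate <- cohort[[1]]$channels[[working_channels()[1]]]$sampling_rate
  m <- ncol(all_samples[[1]]$values)
  x <- array(NA_real_, dim = c(length(all_samples), 4L, m),
             dimnames = list(NULL, working_channels(), NULL))
  for (i in seq_along(all_samples)) x[i, , ] <- all_samples[[i]]$values
  structure(list(
    x = x,
    labels = factor(vapply(all_samples, function(s) as.character(s$label), ""),
                    levels = class_set(class_mode)),
    subject = vapply(all_samples, `[[`, "", "subject_id"),
    window_start = vapply(all_samples, `[[`, 0, "window_start"),
    purity = vapply(all_samples, `[[`, 0, "purity"),
    window_s = window_s, stride_s = stride_s, rate = rate,
    channels = working_channels(), class_mode = class_mode
  ), class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf(
    "<windowed_dataset> %d samples (%d ch x %d pts), window %g s, stride %g s\n",
    dim(x$x)[1], dim(x$x)[2], dim(x$x)[3], x$window_s, x$stride_s))
  print(table(x$labels))
  invisible(x)
}

#' Subset a windowed dataset by sample index
#'
#' @param dataset A `windowed_dataset`.
#' @param idx Integer indices of samples to keep.
#' @return A `windowed_dataset` with the selected samples.
#' @export
subset_dataset <- function(dataset, idx) {
  stopifnot(inherits(dataset, "windowed_dataset"))
  out <- dataset
  out$x <- dataset$x[idx, , , drop = FALSE]
  out$labels <- dataset$labels[idx]
  out$subject <- dataset$subject[idx]
  out$window_start <- dataset$window_start[idx]
  out$purity <- dataset$purity[idx]
  out
}
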