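# Interval features for the forest classifiers: summary statistics per
# random interval (interval-statistics forest) and frequency-domain features
# of one random interval (spectral-interval forest).

#' Summary-statistic features over intervals of a series
#'
#' For each interval `[start, end]` (1-based, inclusive, length >= 3) the
#' features are the mean, the standard deviation and the least-squares slope
#' of the values against time index.
#'
#' @param series Numeric vector.
#' @param intervals Two-column integer matrix of interval starts and ends.
#' @return Numeric vector of length `3 * nrow(intervals)`, ordered
#'   (mean, sd, slope) per interval.
#' @export
interval_stat_features <- function(series, intervals) {
  stopifnot(is.numeric(series), is.matrix(intervals), ncol(intervals) == 2)
  n <- length(series)
  out <- numeric(3L * nrow(intervals))
  for (k in seq_len(nrow(intervals))) {
    i0 <- intervals[k, 1]; i1 <- intervals[k, 2]
    if (i0 < 1 || i1 > n || i1 - i0 + 1 < 3) {
      stop("interval_too_short: need length >= 3 within series bounds",
           call. = FALSE)
    }
    v <- series[i0:i1]
    t <- seq_along(v)
    tc <- t - mean(t)
    out[3 * k - 2] <- mean(v)
    out[3 * k - 1] <- sd(v)
    out[3 * k] <- sum(tc * v) / sum(tc^2)
  }
  out
}

#' Frequency-domain features of one interval
#'
#' Concatenates (i) the power-spectrum magnitudes of the mean-removed
#' interval (bins 1 .. floor(len/2)) and (ii) the autocorrelation
#' coefficients at lags 1 .. min(32, floor(len/4)). Feature length is fixed
#' given the interval length.
#'
#' @param series Numeric vector.
#' @param interval Integer pair `(start, end)`, 1-based inclusive, length
#'   >= 16.
#' @return Numeric feature vector.
#' @export
spectral_features <- function(series, interval) {
  stopifnot(is.numeric(series), length(interval) == 2)
  i0 <- interval[1]; i1 <- interval[2]
  len <- i1 - i0 + 1
  if (i0 < 1 || i1 > length(series) || len < 16) {
    stop("interval_too_short: spectral features need length >= 16",
         call. = FALSE)
  }
  v <- series[i0:i1]
  v <- v - mean(v)
  spec <- Mod(fft(v))[2:(floor(len / 2) + 1)]
  max_lag <- min(32L, floor(len / 4))
  s2 <- sum(v^2)
  ac <- if (s2 == 0) rep(0, max_lag) else {
    vapply(seq_len(max_lag), function(l) {
      sum(v[1:(len - l)] * v[(l + 1):len]) / s2
    }, numeric(1))
  }
  c(spec, ac)
}

# random interval draws used per tree; lengths >= min_len, uniform placement
draw_intervals <- function(m, n_intervals, min_len) {
  starts <- integer(n_intervals); ends <- integer(n_intervals)
  for (k in seq_len(n_intervals)) {
    len <- sample(min_len:m, 1)
    s <- sample(seq_len(m - len + 1L), 1)
    starts[k] <- s; ends[k] <- s + len - 1L
  }
  cbind(start = starts, end = ends)
}
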