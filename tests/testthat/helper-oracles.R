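# Independent oracles and small fixture builders used across tests.

# top-down memoized minimization over all monotone warping paths with steps
# {(1,0),(0,1),(1,1)}; written independently of the package's banded
# dynamic program (R, recursion, no band).
dtw_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  memo <- matrix(NA_real_, n, m)
  rec <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    c0 <- (a[i] - b[j])^2
    best <- if (i == 1 && j == 1) 0
    else min(if (i > 1) rec(i - 1, j) else Inf,
             if (j > 1) rec(i, j - 1) else Inf,
             if (i > 1 && j > 1) rec(i - 1, j - 1) else Inf)
    memo[i, j] <<- c0 + best
    memo[i, j]
  }
  rec(n, m)
}

# literal enumeration of every monotone warping path (exponential; tiny
# inputs only) -- cross-checks the memoized oracle itself
dtw_enumerate <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + (a[i] - b[j])^2
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible())
    }
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    if (i < n && j < m) walk(i + 1, j + 1, acc)
  }
  walk(1, 1, 0)
  best
}

# MCC oracle: Pearson correlation of the reconstructed 0/1 label vectors
mcc_pearson <- function(tp, tn, fp, fn) {
  truth <- c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn))
  pred <- c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn))
  suppressWarnings(cor(truth, pred))
}

# a minimal preprocessed-style recording: 4 working channels of given
# duration at `rate`, values supplied per channel or constant
make_working_recording <- function(annotation, rate = 4, values = NULL,
                                   subject_id = "T01") {
  n <- round(annotation_duration(annotation) * rate)
  chans <- lapply(working_channels(), function(nm) {
    v <- if (is.null(values)) rep(0.5, n) else values[[nm]]
    channel_series(nm, v, rate)
  })
  recording(subject_id, chans, annotation)
}

# a small separable windowed dataset built directly: class B series carry a
# mean shift plus a faster oscillation on every channel
make_separable_dataset <- function(n_per_class = 20, n_channels = 4, m = 64,
                                   seed = 1, sep = 2) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- array(0, dim = c(n, n_channels, m))
  t <- seq_len(m) / m
  for (i in seq_len(n)) {
    stress <- i > n_per_class
    for (c in seq_len(n_channels)) {
      f <- if (stress) 8 else 3
      x[i, c, ] <- (if (stress) sep else 0) + sin(2 * pi * f * t) +
        rnorm(m, 0, 0.3)
    }
  }
  structure(list(
    x = x,
    labels = factor(rep(c("no_stress", "stress"), each = n_per_class),
                    levels = class_set("binary")),
    subject = rep(sprintf("S%02d", rep(1:4, length.out = n)), 1),
    window_start = seq_len(n) * 1.0,
    purity = rep(1, n),
    window_s = m / 4, stride_s = m / 4, rate = 4,
    channels = working_channels()[seq_len(n_channels)],
    class_mode = "binary"
  ), class = "windowed_dataset")
}

# single-channel variant used for the strategy-coincidence checks
make_univariate_dataset <- function(...) {
  make_separable_dataset(..., n_channels = 1)
}

# cached short-profile cohorts shared by the expensive acceptance checks
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(kind = c("strong", "null"), n_subjects = 8,
                          seed = 11) {
  kind <- match.arg(kind)
  key <- paste(kind, n_subjects, seed, sep = "_")
  if (is.null(.cohort_cache[[key]])) {
    cfg <- cohort_config(n_subjects = n_subjects, seed = seed, short = TRUE)
    cfg <- if (kind == "strong") strong_reactivity(cfg) else null_reactivity(cfg)
    .cohort_cache[[key]] <- preprocess_cohort(generate_cohort(cfg))
  }
  .cohort_cache[[key]]
}
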