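# Evaluation protocol: 80/20 split, confusion counts, Matthews correlation
# and accuracy, grid search over window size, stride and classifier
# configuration, and top-k distribution summaries.

#' Split a windowed dataset into train and test indices
#'
#' Sample mode draws a uniform random split at the given fraction; subject
#' mode assigns whole subjects to one side only (recommended when windows
#' overlap, since overlapping windows leak across a sample-wise split).
#' Splits are re-drawn (bounded retries) until both classes appear on both
#' sides.
#'
#' @param dataset A `windowed_dataset` with >= 5 samples.
#' @param fraction Training fraction, default 0.8.
#' @param mode `"sample"` or `"subject"`.
#' @param seed Integer seed.
#' @param max_retries Redraws allowed to satisfy class presence.
#' @return List with `train_ids`, `test_ids`, `fraction`, `mode`, `seed`.
#' @export
split_dataset <- function(dataset, fraction = 0.8,
                          mode = c("sample", "subject"), seed = 1L,
                          max_retries = 100L) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "windowed_dataset"), fraction > 0, fraction < 1)
  n <- length(dataset$labels)
  if (n < 5) stop("too_few_samples: split needs >= 5", call. = FALSE)
  present <- function(idx) nlevels(droplevels(dataset$labels[idx])) >= 2
  for (try in 0:max_retries) {
    train <- with_local_seed(derive_seed(seed, 400L + try), {
      if (mode == "sample") {
        sort(sample.int(n, round(fraction * n)))
      } else {
        subs <- sample(unique(dataset$subject))
        sizes <- vapply(subs, function(s) sum(dataset$subject == s), 0)
        k <- which.min(abs(cumsum(sizes) / n - fraction))
        k <- min(max(k, 1L), length(subs) - 1L)
        which(dataset$subject %in% subs[seq_len(k)])
      }
    })
    test <- setdiff(seq_len(n), train)
    if (length(train) && length(test) && present(train) && present(test)) {
      return(list(train_ids = train, test_ids = test, fraction = fraction,
                  mode = mode, seed = as.integer(seed)))
    }
  }
  stop("class_presence_unsatisfied: could not place both classes on both sides",
       call. = FALSE)
}

#' Confusion counts from true and predicted labels
#'
#' @param true_labels,predicted_labels Equal-length factors over one class
#'   set.
#' @return Integer k x k matrix of (true class, predicted class) counts with
#'   class `confusion_counts`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels) {
  stopifnot(length(true_labels) == length(predicted_labels))
  true_labels <- as.factor(true_labels)
  lev <- levels(true_labels)
  if (!all(as.character(predicted_labels) %in% lev)) {
    stop("unknown_label: prediction outside the class set", call. = FALSE)
  }
  predicted_labels <- factor(as.character(predicted_labels), levels = lev)
  m <- table(true = true_labels, predicted = predicted_labels)
  structure(matrix(as.integer(m), nlevels(true_labels),
                   dimnames = dimnames(m)),
            class = c("confusion_counts", "matrix"))
}

#' @export
print.confusion_counts <- function(x, ...) {
  print(matrix(unclass(x), nrow(x), dimnames = dimnames(x)))
  invisible(x)
}

#' Binary view of a 2x2 confusion matrix
#'
#' The second class (index 1, e.g. `stress`) is the positive class.
#'
#' @param confusion A 2x2 `confusion_counts`.
#' @return Named vector `TP`, `TN`, `FP`, `FN`.
#' @export
binary_counts <- function(confusion) {
  stopifnot(nrow(confusion) == 2, ncol(confusion) == 2)
  c(TP = confusion[2, 2], TN = confusion[1, 1],
    FP = confusion[1, 2], FN = confusion[2, 1])
}

#' Matthews correlation coefficient
#'
#' Binary: `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; with more
#' classes, the generalized multi-category correlation. Any zero factor in
#' the denominator returns 0 by convention.
#'
#' @param confusion A `confusion_counts` (or plain square count matrix).
#' @return Correlation in [-1, 1].
#' @export
mcc <- function(confusion) {
  m <- unclass(confusion) * 1.0
  stopifnot(nrow(m) == ncol(m), sum(m) > 0)
  s <- sum(m)
  tr <- sum(diag(m))
  t_k <- rowSums(m)   # true-class totals
  p_k <- colSums(m)   # predicted-class totals
  num <- tr * s - sum(p_k * t_k)
  den2 <- (s^2 - sum(p_k^2)) * (s^2 - sum(t_k^2))
  if (den2 <= 0) return(0)
  num / sqrt(den2)
}

#' Classification accuracy
#'
#' @param confusion A `confusion_counts`.
#' @return Trace over total, in [0, 1].
#' @export
accuracy <- function(confusion) {
  m <- unclass(confusion)
  stopifnot(sum(m) > 0)
  sum(diag(m)) / sum(m)
}

#' Evaluate one classifier configuration end to end
#'
#' Builds the windowed dataset at the given window and stride, splits it,
#' fits the classifier on the training part, predicts the held-out part and
#' computes the metrics. Fully seeded.
#'
#' @param cohort List of preprocessed [recording()] objects.
#' @param spec A [classifier_spec()].
#' @param window_s,stride_s Window length and stride in seconds.
#' @param split Split settings: list with `fraction`, `mode`, `seed`.
#' @param purity_threshold,class_mode Passed to [build_dataset()].
#' @param dataset Optional prebuilt `windowed_dataset` (skips windowing).
#' @return An `evaluation_result`: spec, window, stride, `mcc`, `accuracy`,
#'   `confusion`, sizes and seeds.
#' @export
evaluate_config <- function(cohort, spec, window_s, stride_s,
                            split = list(fraction = 0.8, mode = "sample",
                                         seed = 1L),
                            purity_threshold = 0.8, class_mode = "binary",
                            dataset = NULL) {
  if (is.null(dataset)) {
    dataset <- build_dataset(cohort, window_s, stride_s,
                             purity_threshold = purity_threshold,
                             class_mode = class_mode)
  }
  sp <- split_dataset(dataset, fraction = split$fraction %||% 0.8,
                      mode = split$mode %||% "sample",
                      seed = split$seed %||% 1L)
  model <- fit_classifier(spec, subset_dataset(dataset, sp$train_ids))
  test <- subset_dataset(dataset, sp$test_ids)
  pred <- predict(model, test)
  conf <- confusion_matrix(test$labels, pred)
  structure(list(spec = spec, window_s = window_s, stride_s = stride_s,
                 mcc = mcc(conf), accuracy = accuracy(conf), confusion = conf,
                 n_train = length(sp$train_ids), n_test = length(sp$test_ids),
                 split_seed = sp$seed),
            class = "evaluation_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Grid search over classifier configurations, windows and strides
#'
#' Evaluates every spec at every window and stride (strides given as
#' fractions of the window). Failures are recorded per grid point and the
#' sweep continues. Results are ranked by MCC descending, ties by accuracy,
#' then insertion order.
#'
#' @param cohort List of preprocessed recordings.
#' @param specs List of [classifier_spec()] objects.
#' @param windows Window lengths in seconds (default the studied
#'   150-1200 s range).
#' @param stride_fractions Strides as fractions of the window.
#' @param split Split settings, see [evaluate_config()].
#' @param purity_threshold,class_mode Passed to [build_dataset()].
#' @return A `grid_search_report`: list with `results`, a tidy `table` and
#'   the `ranking` permutation.
#' @export
grid_search <- function(cohort, specs, windows = c(150, 300, 600, 900, 1200),
                        stride_fractions = c(0.25, 0.5, 1),
                        split = list(fraction = 0.8, mode = "sample",
                                     seed = 1L),
                        purity_threshold = 0.8, class_mode = "binary") {
  stopifnot(length(specs) >= 1, length(windows) >= 1,
            length(stride_fractions) >= 1)
  results <- list()
  rows <- list()
  i <- 0L
  for (w in windows) for (f in stride_fractions) {
    s <- w * f
    dataset <- tryCatch(
      build_dataset(cohort, w, s, purity_threshold = purity_threshold,
                    class_mode = class_mode),
      error = function(e) e)
    for (spec in specs) {
      i <- i + 1L
      res <- if (inherits(dataset, "error")) {
        simpleError(conditionMessage(dataset))
      } else {
        tryCatch(evaluate_config(cohort, spec, w, s, split = split,
                                 dataset = dataset),
                 error = function(e) e)
      }
      failed <- inherits(res, "error")
      results[[i]] <- res
      rows[[i]] <- data.frame(
        family = spec$family, strategy = spec$strategy,
        window_s = w, stride_s = s,
        mcc = if (failed) NA_real_ else res$mcc,
        accuracy = if (failed) NA_real_ else res$accuracy,
        error = if (failed) conditionMessage(res) else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, rows)
  ranking <- order(-ifelse(is.na(table$mcc), -Inf, table$mcc),
                   -ifelse(is.na(table$accuracy), -Inf, table$accuracy),
                   seq_len(nrow(table)))
  structure(list(results = results, table = table, ranking = ranking),
            class = "grid_search_report")
}

#' Distribution summary of the top-k configurations
#'
#' Per classifier family and strategy: median, quartiles, minimum and
#' maximum of MCC and accuracy over that group's k best configurations
#' (by MCC) -- the tabular form behind a violin-style plot of tuning
#' results.
#'
#' @param report A `grid_search_report`.
#' @param k Configurations per group to summarize (default 10).
#' @return Data frame, one row per family x strategy.
#' @export
summarize_top_k <- function(report, k = 10) {
  stopifnot(inherits(report, "grid_search_report"),
            k >= 1, k <= nrow(report$table))
  tab <- report$table[!is.na(report$table$mcc), , drop = FALSE]
  groups <- unique(tab[, c("family", "strategy")])
  out <- lapply(seq_len(nrow(groups)), function(g) {
    sub <- tab[tab$family == groups$family[g] &
                 tab$strategy == groups$strategy[g], , drop = FALSE]
    sub <- sub[order(-sub$mcc, -sub$accuracy), , drop = FALSE]
    sub <- head(sub, k)
    q_m <- quantile(sub$mcc, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    q_a <- quantile(sub$accuracy, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(family = groups$family[g], strategy = groups$strategy[g],
               n = nrow(sub),
               mcc_min = q_m[1], mcc_q1 = q_m[2], mcc_median = q_m[3],
               mcc_q3 = q_m[4], mcc_max = q_m[5],
               acc_min = q_a[1], acc_q1 = q_a[2], acc_median = q_a[3],
               acc_q3 = q_a[4], acc_max = q_a[5],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a grid-search report to JSON
#'
#' @param report A `grid_search_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(list(table = report$table, ranking = report$ranking),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a grid-search report written by [write_report()]
#'
#' @param path JSON path.
#' @return List with `table` (data frame) and `ranking` (integer vector).
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$table$error <- as.character(x$table$error)
  x$ranking <- as.integer(x$ranking)
  x
}
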