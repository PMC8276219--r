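# Interval-statistics and spectral-interval forests: ensembles of bootstrap
# decision trees (sqrt(p) feature subsetting per split via randomForest with
# a single tree), each tree grown on features of freshly drawn random
# intervals of the series.

# vectorized feature construction over all samples (rows of x) -----------

interval_stat_matrix <- function(x, intervals) {
  n <- nrow(x)
  out <- matrix(0, n, 3L * nrow(intervals))
  for (k in seq_len(nrow(intervals))) {
    v <- x[, intervals[k, 1]:intervals[k, 2], drop = FALSE]
    len <- ncol(v)
    mu <- rowMeans(v)
    va <- (rowSums(v^2) - len * mu^2) / (len - 1)
    tc <- seq_len(len) - (len + 1) / 2
    out[, 3 * k - 2] <- mu
    out[, 3 * k - 1] <- sqrt(pmax(va, 0))
    out[, 3 * k] <- as.numeric(v %*% tc) / sum(tc^2)
  }
  out
}

spectral_matrix <- function(x, interval) {
  v <- x[, interval[1]:interval[2], drop = FALSE]
  len <- ncol(v)
  v <- v - rowMeans(v)
  spec <- Mod(t(stats::mvfft(t(v))))[, 2:(floor(len / 2) + 1), drop = FALSE]
  max_lag <- min(32L, floor(len / 4))
  s2 <- rowSums(v^2)
  ac <- vapply(seq_len(max_lag), function(l) {
    num <- rowSums(v[, 1:(len - l), drop = FALSE] *
                     v[, (l + 1):len, drop = FALSE])
    ifelse(s2 == 0, 0, num / s2)
  }, numeric(nrow(v)))
  if (nrow(v) == 1) ac <- matrix(ac, nrow = 1)
  cbind(spec, ac)
}

tree_features <- function(x, family, intervals) {
  if (family == "interval_forest") interval_stat_matrix(x, intervals)
  else spectral_matrix(x, intervals[1, ])
}

#' Train an interval-based random forest on univariate series
#'
#' Each of the `n_trees` trees draws its own random intervals
#' (interval-statistics forest: `ceiling(sqrt(m))` intervals of length >= 3,
#' features mean/sd/slope; spectral-interval forest: one interval of length
#' >= 16, features power spectrum + autocorrelation), computes features for
#' all training series, and grows one bootstrap CART tree with `sqrt(p)`
#' random feature candidates per split. Reproducible from `seed`.
#'
#' @param x Numeric matrix, one series per row.
#' @param labels Factor of class labels (>= 2 classes present).
#' @param family `"interval_forest"` or `"spectral_forest"`.
#' @param n_trees Number of trees.
#' @param seed Integer seed.
#' @return An object of class `interval_forest_model`.
#' @export
train_forest <- function(x, labels, family = c("interval_forest",
                                               "spectral_forest"),
                         n_trees = 100, seed = 1L) {
  family <- match.arg(family)
  stopifnot(is.matrix(x), nrow(x) == length(labels), n_trees >= 1)
  labels <- as.factor(labels)
  present <- droplevels(labels)
  if (nlevels(present) < 2) {
    stop("single_class_training: forest needs >= 2 classes", call. = FALSE)
  }
  m <- ncol(x)
  min_len <- if (family == "interval_forest") 3L else 16L
  if (m < min_len) stop("series_too_short for ", family, call. = FALSE)
  n_int <- if (family == "interval_forest") as.integer(ceiling(sqrt(m))) else 1L
  trees <- lapply(seq_len(n_trees), function(t) {
    with_local_seed(derive_seed(seed, 7000L + t), {
      intervals <- draw_intervals(m, n_int, min_len)
      feats <- tree_features(x, family, intervals)
      fit <- randomForest::randomForest(
        feats, present, ntree = 1,
        mtry = max(1L, floor(sqrt(ncol(feats)))))
      list(fit = fit, intervals = intervals)
    })
  })
  structure(list(trees = trees, family = family, m = m,
                 levels = levels(labels), present = levels(present)),
            class = "interval_forest_model")
}

#' Predict with an interval forest
#'
#' Majority vote over the per-tree predictions; ties break toward the lowest
#' class index.
#'
#' @param model An `interval_forest_model` from [train_forest()].
#' @param x Numeric matrix of series, same length as at training.
#' @return Factor of predicted labels with the training levels.
#' @export
forest_predict <- function(model, x) {
  stopifnot(inherits(model, "interval_forest_model"), is.matrix(x))
  if (ncol(x) != model$m) {
    stop("dimension_mismatch: series length ", ncol(x), " != ", model$m,
         call. = FALSE)
  }
  votes <- matrix(0L, nrow(x), length(model$levels))
  for (tr in model$trees) {
    feats <- tree_features(x, model$family, tr$intervals)
    p <- as.character(predict(tr$fit, feats))
    ci <- match(p, model$levels)
    votes[cbind(seq_len(nrow(x)), ci)] <- votes[cbind(seq_len(nrow(x)), ci)] + 1L
  }
  factor(model$levels[apply(votes, 1, which.max)], levels = model$levels)
}
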