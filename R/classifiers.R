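# Classifier zoo: DTW nearest neighbour, interval-statistics forest,
# spectral-interval forest and the FCN, each usable under two multivariate
# strategies -- one homogeneous classifier per channel combined by majority
# vote (ensemble), or a single classifier on the concatenated channels.

CLASSIFIER_FAMILIES <- c("dtw_1nn", "interval_forest", "spectral_forest", "fcn")
MULTIVARIATE_STRATEGIES <- c("ensemble", "concatenate")

default_hyperparameters <- function(family) {
  switch(family,
    dtw_1nn = list(band_fraction = 0.1, k = 1),
    interval_forest = list(n_trees = 100),
    spectral_forest = list(n_trees = 100),
    fcn = list(widths = c(64, 128, 64), kernels = c(8, 5, 3), epochs = 20,
               learning_rate = 1e-3, batch_size = 32, literal_concat = FALSE))
}

#' Specify a classifier configuration
#'
#' @param family One of `"dtw_1nn"`, `"interval_forest"`,
#'   `"spectral_forest"`, `"fcn"`.
#' @param strategy `"ensemble"` (one classifier per channel, majority vote)
#'   or `"concatenate"` (one classifier on the appended channels).
#' @param hyperparameters Named list overriding the family defaults.
#' @param seed Integer seed governing fitting.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = CLASSIFIER_FAMILIES,
                            strategy = MULTIVARIATE_STRATEGIES,
                            hyperparameters = list(), seed = 1L) {
  family <- match.arg(family)
  strategy <- match.arg(strategy)
  hp <- utils::modifyList(default_hyperparameters(family), hyperparameters)
  structure(list(family = family, strategy = strategy, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Append the channels of one sample into a single series
#'
#' Channels are appended in the fixed working order (`bvp`, `eda`, `temp`,
#' `acc` for four-channel samples); values are unchanged, so the first `m`
#' values of the result equal the first channel exactly.
#'
#' @param sample Channel-by-time numeric matrix.
#' @return Numeric vector of length `nrow(sample) * ncol(sample)`.
#' @export
concatenate_channels <- function(sample) {
  stopifnot(is.matrix(sample))
  as.numeric(t(sample))
}

# one channel of a dataset array as an (n x m) matrix, robust to n = 1
channel_matrix <- function(x, c) matrix(x[, c, ], nrow = dim(x)[1])

# dataset array (n x c x m) -> concatenated matrix (n x c*m)
concat_dataset <- function(x) {
  do.call(cbind, lapply(seq_len(dim(x)[2]), function(c) channel_matrix(x, c)))
}

#' Majority vote over per-channel predictions
#'
#' @param per_channel_labels List of equal-length factors sharing one level
#'   set (one element per channel classifier).
#' @return Factor of winning labels; ties break toward the lowest class
#'   index.
#' @export
majority_vote <- function(per_channel_labels) {
  if (!length(per_channel_labels)) stop("empty_votes", call. = FALSE)
  lev <- levels(per_channel_labels[[1]])
  n <- length(per_channel_labels[[1]])
  votes <- matrix(0L, n, length(lev))
  for (v in per_channel_labels) {
    stopifnot(identical(levels(v), lev), length(v) == n)
    ci <- as.integer(v)
    votes[cbind(seq_len(n), ci)] <- votes[cbind(seq_len(n), ci)] + 1L
  }
  factor(lev[apply(votes, 1, which.max)], levels = lev)
}

channel_seed <- function(seed, c) derive_seed(seed, 100L + c)

fit_one <- function(spec, x_mat_or_arr, labels, seed) {
  hp <- spec$hyperparameters
  switch(spec$family,
    dtw_1nn = list(kind = "dtw", train_x = x_mat_or_arr,
                   train_labels = labels,
                   band_fraction = hp$band_fraction, k = hp$k),
    interval_forest = ,
    spectral_forest = train_forest(x_mat_or_arr, labels, spec$family,
                                   n_trees = hp$n_trees, seed = seed),
    fcn = {
      net <- build_fcn(dim(x_mat_or_arr)[3], dim(x_mat_or_arr)[2],
                       nlevels(labels), widths = hp$widths,
                       kernels = hp$kernels, seed = seed)
      train_fcn(net, x_mat_or_arr, labels, epochs = hp$epochs,
                learning_rate = hp$learning_rate,
                batch_size = hp$batch_size, seed = seed)
    })
}

predict_one <- function(spec, model, x_mat_or_arr) {
  switch(spec$family,
    dtw_1nn = {
      lev <- levels(model$train_labels)
      out <- character(nrow(x_mat_or_arr))
      for (i in seq_len(nrow(x_mat_or_arr))) {
        d <- .dtw_dists_cpp(model$train_x, x_mat_or_arr[i, ],
                            model$band_fraction)
        if (model$k <= 1) {
          best <- which(d == min(d))
          if (length(best) > 1) {
            ci <- as.integer(model$train_labels[best])
            best <- best[ci == min(ci)][1]
          }
          out[i] <- as.character(model$train_labels[best])
        } else {
          nn <- order(d)[seq_len(min(model$k, length(d)))]
          cnt <- tabulate(as.integer(model$train_labels[nn]), length(lev))
          out[i] <- lev[which.max(cnt)]
        }
      }
      factor(out, levels = lev)
    },
    interval_forest = ,
    spectral_forest = forest_predict(model, x_mat_or_arr),
    fcn = fcn_predict(model, x_mat_or_arr)$label)
}

#' Fit a classifier on a windowed dataset
#'
#' Under the ensemble strategy one homogeneous classifier is trained per
#' channel and predictions are combined by [majority_vote()]; under
#' concatenation a single classifier sees the appended channels. For the FCN
#' the concatenation strategy feeds the channels as parallel convolution
#' input channels (literal temporal appending would create spurious
#' cross-channel boundaries for the convolutions; set hyperparameter
#' `literal_concat = TRUE` to append literally instead).
#'
#' @param spec A [classifier_spec()].
#' @param dataset A `windowed_dataset` with >= 2 classes present.
#' @return An object of class `stress_classifier`.
#' @export
fit_classifier <- function(spec, dataset) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(dataset, "windowed_dataset"))
  labels <- dataset$labels
  if (nlevels(droplevels(labels)) < 2) {
    stop("single_class_training: need >= 2 classes", call. = FALSE)
  }
  x <- dataset$x
  n_ch <- dim(x)[2]
  models <- if (spec$strategy == "ensemble") {
    lapply(seq_len(n_ch), function(c) {
      inp <- if (spec$family == "fcn") x[, c, , drop = FALSE]
             else channel_matrix(x, c)
      fit_one(spec, inp, labels, channel_seed(spec$seed, c))
    })
  } else {
    inp <- if (spec$family == "fcn" && !isTRUE(spec$hyperparameters$literal_concat)) {
      x
    } else if (spec$family == "fcn") {
      cc <- concat_dataset(x)
      array(cc, dim = c(nrow(cc), 1L, ncol(cc)))
    } else {
      concat_dataset(x)
    }
    list(fit_one(spec, inp, labels, channel_seed(spec$seed, 1L)))
  }
  structure(list(spec = spec, models = models, levels = levels(labels),
                 n_channels = n_ch, m = dim(x)[3]),
            class = "stress_classifier")
}

#' Predict window labels with a fitted classifier
#'
#' @param object A `stress_classifier` from [fit_classifier()].
#' @param newdata A `windowed_dataset` or a sample array (n x channels x
#'   time) with the training dimensions.
#' @param ... Unused.
#' @return Factor of predicted labels drawn from the training class set.
#' @export
predict.stress_classifier <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "windowed_dataset")) newdata$x else newdata
  stopifnot(length(dim(x)) == 3)
  if (dim(x)[2] != object$n_channels || dim(x)[3] != object$m) {
    stop("dimension_mismatch: expected ", object$n_channels, " x ", object$m,
         " samples", call. = FALSE)
  }
  spec <- object$spec
  if (spec$strategy == "ensemble") {
    per_channel <- lapply(seq_along(object$models), function(c) {
      inp <- if (spec$family == "fcn") x[, c, , drop = FALSE]
             else channel_matrix(x, c)
      predict_one(spec, object$models[[c]], inp)
    })
    majority_vote(per_channel)
  } else {
    inp <- if (spec$family == "fcn" && !isTRUE(spec$hyperparameters$literal_concat)) {
      x
    } else if (spec$family == "fcn") {
      cc <- concat_dataset(x)
      array(cc, dim = c(nrow(cc), 1L, ncol(cc)))
    } else {
      concat_dataset(x)
    }
    predict_one(spec, object$models[[1]], inp)
  }
}
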