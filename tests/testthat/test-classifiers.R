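test_that("dtw_distance matches worked examples and the path oracle", {
  expect_equal(dtw_distance(c(0, 0), c(1, 1)), 2)
  expect_equal(dtw_distance(1:5, 1:5), 0)
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 2, 3)), 0) # warping absorbs it
  a <- c(0, 1, 2); b <- c(5, 5)
  expect_equal(dtw_distance(a, b), dtw_distance(b, a)) # symmetric

  set.seed(7)
  for (rep in 1:25) {
    n <- sample(2:9, 1); m <- sample(2:9, 1)
    x <- round(rnorm(n), 2); y <- round(rnorm(m), 2)
    expect_equal(dtw_distance(x, y), dtw_oracle(x, y))
    expect_equal(dtw_oracle(x, y), dtw_enumerate(x, y)) # oracle self-check
  }

  # a banded distance can only be >= the unconstrained one
  set.seed(8)
  x <- rnorm(40); y <- rnorm(40)
  expect_gte(dtw_distance(x, y, band_fraction = 0.1), dtw_distance(x, y))
  expect_error(dtw_distance(numeric(0), 1:3), "empty_sequence")
  expect_error(dtw_distance(1:50, 1:2, band_fraction = 0.05),
               "band_too_narrow")
})

test_that("1-NN under DTW picks the closest series with stable tie-breaks", {
  train <- rbind(c(0, 0, 0, 0), c(1, 1, 1, 1), c(5, 5, 5, 5))
  lab <- factor(c("no_stress", "stress", "stress"),
                levels = class_set("binary"))
  expect_equal(as.character(predict_1nn_dtw(train, lab, c(0.1, 0, 0.1, 0))),
               "no_stress")
  expect_equal(as.character(predict_1nn_dtw(train, lab, c(4.6, 5, 5, 4.9))),
               "stress")
  # exact distance tie between rows 1 and 2 -> lowest class index wins
  tie_train <- rbind(c(0, 0), c(1, 1))
  tie_lab <- factor(c("stress", "no_stress"), levels = class_set("binary"))
  expect_equal(as.character(predict_1nn_dtw(tie_train, tie_lab, c(0.5, 0.5))),
               "no_stress")
  expect_error(predict_1nn_dtw(train, lab, c(1, 2)), "dimension_mismatch")
})

test_that("interval features reproduce hand-computed statistics", {
  s <- c(1, 2, 3, 4, 5, 10)
  f <- interval_stat_features(s, rbind(c(1, 5), c(2, 4)))
  expect_equal(f[1:3], c(3, sd(1:5), 1))       # linear ramp: slope exactly 1
  expect_equal(f[4:6], c(3, 1, 1))
  expect_error(interval_stat_features(s, rbind(c(1, 2))), "interval_too_short")

  # a pure sinusoid with k cycles peaks at spectrum bin k
  len <- 64
  for (k in c(2, 5, 13)) {
    v <- sin(2 * pi * k * (0:(len - 1)) / len)
    sp <- spectral_features(v, c(1, len))
    spec_part <- sp[seq_len(len / 2)]
    expect_equal(which.max(spec_part), k)
  }
  # white-noise autocorrelations stay within the sampling bound
  set.seed(3)
  v <- rnorm(512)
  sp <- spectral_features(v, c(1, 512))
  ac <- tail(sp, 32)
  expect_lt(max(abs(ac)), 4 / sqrt(512))
  expect_error(spectral_features(v, c(1, 10)), "interval_too_short")
})

test_that("interval and spectral forests learn a separable problem", {
  ds <- make_univariate_dataset(n_per_class = 25, m = 64, seed = 4)
  x <- channel_matrix(ds$x, 1)
  for (fam in c("interval_forest", "spectral_forest")) {
    fit <- train_forest(x, ds$labels, fam, n_trees = 50, seed = 2)
    pred <- forest_predict(fit, x)
    expect_gt(mean(pred == ds$labels), 0.95)
    # refit with the same seed is identical in its predictions
    fit2 <- train_forest(x, ds$labels, fam, n_trees = 50, seed = 2)
    expect_identical(forest_predict(fit2, x), pred)
  }
  one <- train_forest(x, ds$labels, "interval_forest", n_trees = 1, seed = 1)
  expect_length(one$trees, 1)
  expect_s3_class(forest_predict(one, x), "factor")
  expect_error(train_forest(x, factor(rep("stress", nrow(x)),
                                      levels = class_set("binary")),
                            "interval_forest"),
               "single_class_training")
  expect_error(forest_predict(one, x[, 1:10, drop = FALSE]),
               "dimension_mismatch")
})

test_that("fcn parameter count matches the closed form and outputs are sane", {
  net <- build_fcn(32, n_channels = 2, n_classes = 3,
                   widths = c(4, 6, 5), kernels = c(8, 5, 3), seed = 1)
  manual <- (2 * 8 * 4 + 2 * 4) + (4 * 5 * 6 + 2 * 6) + (6 * 3 * 5 + 2 * 5) +
    (5 * 3 + 3)
  expect_equal(fcn_param_count(net), manual)

  set.seed(1)
  x <- array(rnorm(10 * 2 * 32), dim = c(10, 2, 32))
  p <- fcn_predict(net, x)
  expect_equal(dim(p$prob), c(10L, 3L))
  expect_equal(rowSums(p$prob), rep(1, 10), tolerance = 1e-12)
  expect_true(all(p$prob >= 0))
  expect_error(build_fcn(0, 1, 2), "invalid_dimensions")
})

test_that("fcn training is deterministic and can overfit a small problem", {
  ds <- make_separable_dataset(n_per_class = 10, n_channels = 2, m = 32,
                               seed = 5, sep = 2)
  net <- build_fcn(32, 2, 2, widths = c(8, 8, 8), kernels = c(8, 5, 3),
                   seed = 3)
  fit <- train_fcn(net, ds$x, ds$labels, epochs = 120, learning_rate = 5e-3,
                   batch_size = 8, seed = 9)
  pred <- fcn_predict(fit, ds$x)$label
  expect_gt(mean(pred == ds$labels), 0.95)
  expect_lt(tail(fit$history, 1), fit$history[1]) # loss decreased

  fit2 <- train_fcn(net, ds$x, ds$labels, epochs = 120, learning_rate = 5e-3,
                    batch_size = 8, seed = 9)
  expect_identical(fcn_predict(fit2, ds$x)$prob, fcn_predict(fit, ds$x)$prob)

  # zero learning rate leaves every learnable weight untouched
  frozen <- train_fcn(net, ds$x, ds$labels, epochs = 2, learning_rate = 0,
                      batch_size = 8, seed = 9)
  expect_identical(frozen$Wd, net$Wd)
  expect_identical(frozen$layers[[1]]$W, net$layers[[1]]$W)
  expect_identical(frozen$layers[[2]]$gamma, net$layers[[2]]$gamma)
})

test_that("majority_vote and concatenate_channels follow their conventions", {
  lev <- class_set("binary")
  a <- factor(c("stress", "stress", "no_stress"), levels = lev)
  b <- factor(c("stress", "no_stress", "no_stress"), levels = lev)
  c_ <- factor(c("no_stress", "stress", "stress"), levels = lev)
  expect_equal(as.character(majority_vote(list(a, b, c_))),
               c("stress", "stress", "no_stress"))
  # a 1-1 tie breaks toward the lowest class index
  expect_equal(as.character(majority_vote(list(a, c_))[3]), "no_stress")
  expect_error(majority_vote(list()), "empty_votes")

  m <- rbind(bvp = 1:3, eda = 4:6)
  expect_equal(concatenate_channels(m), c(1, 2, 3, 4, 5, 6))
})

test_that("every family and strategy fits and predicts a separable dataset", {
  ds <- make_separable_dataset(n_per_class = 12, n_channels = 4, m = 32,
                               seed = 6, sep = 2)
  small_hp <- list(
    dtw_1nn = list(),
    interval_forest = list(n_trees = 25),
    spectral_forest = list(n_trees = 25),
    fcn = list(widths = c(8, 8, 8), epochs = 40, learning_rate = 5e-3,
               batch_size = 8))
  for (fam in CLASSIFIER_FAMILIES) {
    for (strat in MULTIVARIATE_STRATEGIES) {
      spec <- classifier_spec(fam, strat, hyperparameters = small_hp[[fam]],
                              seed = 2)
      model <- fit_classifier(spec, ds)
      pred <- predict(model, ds)
      expect_s3_class(pred, "factor")
      expect_identical(levels(pred), class_set("binary"))
      expect_gt(mean(pred == ds$labels), 0.8)
    }
  }
  bad <- ds$x[, 1:2, , drop = FALSE]
  spec <- classifier_spec("dtw_1nn", "concatenate")
  model <- fit_classifier(spec, ds)
  expect_error(predict(model, bad), "dimension_mismatch")
})
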