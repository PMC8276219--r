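test_that("split_dataset produces disjoint, exhaustive 80/20 splits", {
  ds <- make_separable_dataset(n_per_class = 25, seed = 2) # 50 samples
  sp <- split_dataset(ds, fraction = 0.8, mode = "sample", seed = 5)
  expect_length(sp$train_ids, 40)
  expect_length(sp$test_ids, 10)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), 1:50)
  # both classes on both sides
  expect_equal(nlevels(droplevels(ds$labels[sp$test_ids])), 2)
  # deterministic given the seed, different under another seed
  expect_identical(split_dataset(ds, seed = 5), sp)
  expect_false(identical(split_dataset(ds, seed = 6)$test_ids, sp$test_ids))

  sub <- split_dataset(ds, fraction = 0.8, mode = "subject", seed = 3)
  train_subj <- unique(ds$subject[sub$train_ids])
  test_subj <- unique(ds$subject[sub$test_ids])
  expect_length(intersect(train_subj, test_subj), 0)

  tiny <- subset_dataset(ds, 1:4)
  expect_error(split_dataset(tiny), "too_few_samples")
})

test_that("confusion_matrix counts by true and predicted class", {
  lev <- class_set("binary")
  truth <- factor(c("stress", "stress", "no_stress", "no_stress", "stress"),
                  levels = lev)
  pred <- factor(c("stress", "no_stress", "no_stress", "stress", "stress"),
                 levels = lev)
  cm <- confusion_matrix(truth, pred)
  expect_equal(unname(binary_counts(cm)), c(2L, 1L, 1L, 1L)) # TP TN FP FN
  expect_equal(sum(cm), 5)
  expect_error(confusion_matrix(truth, c("stress", "x", "a", "b", "c")),
               "unknown_label")
})

test_that("mcc matches the closed form and the Pearson oracle", {
  cm <- matrix(c(80L, 20L, 10L, 90L), 2, 2) # TN=80 FN=20 FP=10 TP=90
  expect_equal(mcc(cm), 7000 / sqrt(100 * 110 * 90 * 100))
  expect_equal(mcc(cm), 0.70352647, tolerance = 1e-7)
  expect_equal(accuracy(cm), 0.85)
  expect_equal(mcc(cm), mcc_pearson(tp = 90, tn = 80, fp = 10, fn = 20),
               tolerance = 1e-12)
  # perfect, inverted and degenerate tables
  expect_equal(mcc(matrix(c(50L, 0L, 0L, 50L), 2)), 1)
  expect_equal(mcc(matrix(c(0L, 50L, 50L, 0L), 2)), -1)
  expect_equal(mcc(matrix(c(100L, 0L, 0L, 0L), 2)), 0) # zero denominator
  # label-swap invariance
  set.seed(1)
  for (rep in 1:20) {
    m <- matrix(sample.int(40, 4), 2)
    expect_equal(mcc(m), mcc(m[2:1, 2:1]))
  }
})

test_that("accuracy rewards the majority guess that mcc exposes", {
  # guessing the majority class on a 90/10 imbalance: high accuracy, zero mcc
  truth <- factor(rep(c("no_stress", "stress"), c(90, 10)),
                  levels = class_set("binary"))
  pred <- factor(rep("no_stress", 100), levels = class_set("binary"))
  cm <- confusion_matrix(truth, pred)
  expect_equal(accuracy(cm), 0.9)
  expect_equal(mcc(cm), 0)
})

test_that("evaluate_config ties the pipeline together deterministically", {
  coh <- cached_cohort("strong", n_subjects = 8, seed = 11)
  spec <- classifier_spec("interval_forest", "concatenate",
                          hyperparameters = list(n_trees = 50), seed = 4)
  res <- evaluate_config(coh, spec, window_s = 60, stride_s = 30,
                         split = list(fraction = 0.8, mode = "sample",
                                      seed = 2))
  expect_s3_class(res, "evaluation_result")
  expect_equal(res$n_train + res$n_test, 120)
  expect_equal(sum(res$confusion), res$n_test)
  expect_gte(res$mcc, -1); expect_lte(res$mcc, 1)
  res2 <- evaluate_config(coh, spec, 60, 30,
                          split = list(fraction = 0.8, mode = "sample",
                                       seed = 2))
  expect_identical(res2$mcc, res$mcc)
  expect_identical(res2$confusion, res$confusion)
})

test_that("grid_search sweeps the grid and ranks by mcc", {
  coh <- cached_cohort("strong", n_subjects = 8, seed = 11)
  specs <- list(
    classifier_spec("interval_forest", "concatenate",
                    hyperparameters = list(n_trees = 25), seed = 1),
    classifier_spec("dtw_1nn", "concatenate", seed = 1))
  rep <- grid_search(coh, specs, windows = c(30, 60),
                     stride_fractions = c(0.5, 1),
                     split = list(fraction = 0.8, mode = "sample", seed = 2))
  expect_equal(nrow(rep$table), 8) # 2 windows x 2 strides x 2 specs
  expect_length(rep$results, 8)
  ok <- !is.na(rep$table$mcc)
  expect_true(any(ok))
  best <- rep$ranking[1]
  expect_equal(rep$table$mcc[best], max(rep$table$mcc[ok]))

  top <- summarize_top_k(rep, k = 2)
  expect_true(all(top$mcc_median >= top$mcc_min & top$mcc_median <= top$mcc_max))
  expect_true(all(top$n <= 2))

  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$table$mcc, rep$table$mcc)
  expect_equal(back$table$family, rep$table$family)
  expect_equal(back$ranking, rep$ranking)
})
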