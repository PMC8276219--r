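test_that("count_windows follows the floor law", {
  expect_equal(count_windows(600, 60, 30), 19L)
  expect_equal(count_windows(600, 600, 300), 1L)
  expect_equal(count_windows(100, 60, 30), 2L)
  expect_equal(count_windows(50, 60, 30), 0L)
  # floating-point grid points land on the exact count
  expect_equal(count_windows(0.9, 0.3, 0.2), 4L)
  expect_error(count_windows(100, 0, 10), "invalid_windowing")
  expect_error(count_windows(100, 10, -1), "invalid_windowing")
})

test_that("interval labeling uses majority class, purity and tie convention", {
  ann <- phase_annotation(c(0, 300), c(300, 600),
                          c("baseline", "mental_stress"))
  pure <- label_for_interval(ann, 0, 100)
  expect_equal(as.character(pure$label), "no_stress")
  expect_equal(pure$purity, 1)

  mostly <- label_for_interval(ann, 250, 550, purity_threshold = 0.8)
  expect_equal(as.character(mostly$label), "stress")
  expect_equal(mostly$purity, 250 / 300)

  # 50/50 across the boundary: tie breaks toward the lowest class index
  tie <- label_for_interval(ann, 200, 400, purity_threshold = 0.5)
  expect_equal(as.character(tie$label), "no_stress")
  expect_equal(tie$purity, 0.5)

  # below threshold the window is dropped
  expect_null(label_for_interval(ann, 200, 400, purity_threshold = 0.8))
  expect_error(label_for_interval(ann, -10, 50), "interval_outside_annotation")

  # ternary keeps the stressor identity
  tern <- label_for_interval(ann, 350, 450, class_mode = "ternary")
  expect_equal(as.character(tern$label), "mental_stress")
})

test_that("extract_windows slices the channel grid exactly", {
  ann <- phase_annotation(c(0, 300), c(300, 600),
                          c("baseline", "mental_stress"))
  vals <- lapply(working_channels(), function(nm) seq_len(2400) / 2400)
  names(vals) <- working_channels()
  rec <- make_working_recording(ann, rate = 4, values = vals)

  wins <- extract_windows(rec, window_s = 60, stride_s = 30)
  # 19 grid positions; only the window starting at 270 s straddles the
  # 300 s phase boundary 50/50 and is dropped at the 0.8 purity threshold
  expect_length(wins, 18)
  w1 <- wins[[1]]
  expect_equal(dim(w1$values), c(4L, 240L))
  expect_equal(unname(w1$values["bvp", ]), seq_len(240) / 2400)
  expect_equal(w1$window_start, 0)
  # a window starting at 120 s begins at sample index 480 + 1
  w5 <- wins[[which(vapply(wins, `[[`, 0, "window_start") == 120)]]
  expect_equal(unname(w5$values["eda", 1]), 481 / 2400)
  # per-window scaling spans [0, 1] inside every window
  scaled <- extract_windows(rec, 60, 30, scale_per_window = TRUE)
  expect_equal(unname(range(scaled[[1]]$values["temp", ])), c(0, 1))

  expect_error(extract_windows(rec, 700, 30), "window_longer_than_recording")
})

test_that("build_dataset assembles the cohort corpus with known counts", {
  coh <- cached_cohort("strong", n_subjects = 8, seed = 11)
  ds <- build_dataset(coh, window_s = 60, stride_s = 30)
  # short profile: 19 grid positions per subject, 4 dropped at the 50/50
  # phase boundaries -> 15 windows per subject
  expect_equal(dim(ds$x), c(120L, 4L, 240L))
  expect_equal(length(ds$labels), 120L)
  expect_equal(unname(table(ds$labels)["no_stress"]), 72L) # 60/40 class ratio
  expect_equal(unname(table(ds$labels)["stress"]), 48L)
  expect_setequal(unique(ds$subject), sprintf("S%02d", 1:8))
  expect_true(all(ds$purity >= 0.8))

  sub <- subset_dataset(ds, 1:10)
  expect_equal(dim(sub$x), c(10L, 4L, 240L))
  expect_identical(sub$labels, ds$labels[1:10])

  # a purity threshold of 1 with a full-session window drops everything
  expect_error(build_dataset(coh, 600, 300, purity_threshold = 1),
               "empty_dataset")
})
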