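test_that("min-max normalization follows the stated order of operations", {
  expect_equal(normalize_minmax(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalize_minmax(c(5, 5, 5)), c(0, 0, 0))
  # min/max over non-missing values first, imputation afterwards
  expect_equal(impute_missing(normalize_minmax(c(0, NA, 2))), c(0, 0, 1))
  expect_error(normalize_minmax(c(NA_real_, NA_real_)), "all-missing")

  # bounds and idempotence on random inputs
  set.seed(1)
  for (i in 1:20) {
    x <- stats::rnorm(50, sample(-5:5, 1), runif(1, 0.1, 10))
    y <- normalize_minmax(x)
    expect_true(all(y >= 0 & y <= 1))
    expect_equal(normalize_minmax(y), y, tolerance = 1e-12)
  }
})

test_that("imputation zeroes missing values and nothing else", {
  expect_equal(impute_missing(c(NA, 1)), c(0, 1))
  x <- c(0.5, -1, 2)
  expect_identical(impute_missing(x), x)
  set.seed(2)
  x <- stats::rnorm(100)
  x[sample(100, 20)] <- NA
  y <- impute_missing(x)
  expect_gte(sum(y == 0), 20)
  expect_identical(y[!is.na(x)], x[!is.na(x)])
})

test_that("label projection follows the bin-start convention", {
  g <- project_event_labels(data.frame(start = 12, end = 23), 30)
  expect_identical(which(g == 1L), 13:23)  # seconds 12..22, 0-based
  expect_identical(sum(g), 11L)

  # an event spanning a window boundary marks seconds in both windows
  g2 <- project_event_labels(data.frame(start = 25, end = 40), 60)
  win <- matrix(g2[1:60], nrow = 30)
  expect_identical(which(win[, 1] == 1L), 26:30)  # window 0: seconds 25-29
  expect_identical(which(win[, 2] == 1L), 1:10)   # window 1: seconds 0-9

  expect_identical(project_event_labels(NULL, 45), integer(45))
  expect_error(project_event_labels(data.frame(start = 10, end = 50), 30),
               "outside")
})

test_that("label projection agrees with the per-second membership oracle", {
  set.seed(3)
  for (i in 1:200) {
    duration <- runif(1, 60, 400)
    ev <- random_event_set(duration)
    expect_identical(project_event_labels(ev, duration),
                     oracle_label_grid(ev, duration))
    # conservation: positives = sum over events of ceil(end) - ceil(start)
    expect_identical(sum(project_event_labels(ev, duration)),
                     as.integer(sum(pmin(ceiling(ev$end),
                                         floor(duration)) -
                                    ceiling(ev$start))))
  }
})

test_that("segmentation partitions the recording into 30-s windows", {
  rec <- structure(list(subject_id = "A", fs = 80,
                        samples = rep(0.5, 7 * 3600 * 80),
                        events = data.frame(start = numeric(0),
                                            end = numeric(0)),
                        duration = 7 * 3600),
                   class = "apnea_recording")
  w <- segment_windows(rec)
  expect_length(w, 840L)
  expect_true(all(vapply(w, function(x) length(x$samples), integer(1)) == 2400L))
  expect_true(all(vapply(w, function(x) length(x$labels), integer(1)) == 30L))
  expect_identical(vapply(w, `[[`, numeric(1), "start_time"),
                   seq(0, by = 30, length.out = 840))

  # trailing partial window dropped; concatenation reproduces the kept signal
  rec2 <- structure(list(subject_id = "B", fs = 4,
                         samples = stats::rnorm(45 * 4),
                         events = data.frame(start = 2, end = 14),
                         duration = 45),
                    class = "apnea_recording")
  w2 <- segment_windows(rec2)
  expect_length(w2, 1L)
  expect_identical(w2[[1]]$samples, rec2$samples[1:120])
  expect_identical(which(w2[[1]]$labels == 1L), 3:14)  # seconds 2..13

  rec2$samples <- rec2$samples[1:100]  # 25 s: shorter than one window
  expect_length(segment_windows(rec2), 0L)
})

test_that("windows assemble into the batch tensor contract", {
  cfg <- tiny_synth_config(seed = 21L, n_subjects = 1L,
                           quota = c(none = 0L, mild = 0L,
                                     moderate = 0L, severe = 1L),
                           fs = 80, duration = c(0.04, 0.05))
  co <- generate_cohort(cfg)
  w <- preprocess_recording(co[[1]])
  ds <- windows_to_dataset(w[1:4], fs = 80)
  expect_identical(dim(ds$X), c(4L, 2400L, 1L))
  expect_identical(dim(ds$y), c(4L, 30L))
  for (k in 1:4) expect_identical(as.vector(ds$X[k, , 1]), w[[k]]$samples)

  empty <- windows_to_dataset(list())
  expect_identical(dim(empty$X)[1], 0L)

  w_bad <- w[1:2]
  w_bad[[2]]$samples <- w_bad[[2]]$samples[1:100]
  expect_error(windows_to_dataset(w_bad), "mixed")

  # all preprocessed samples are finite and inside [0, 1]
  expect_true(all(is.finite(ds$X)))
  expect_true(all(ds$X >= 0 & ds$X <= 1))
})

test_that("per-window normalization is available as an alternative scope", {
  cfg <- tiny_synth_config(seed = 22L, n_subjects = 1L,
                           quota = c(none = 0L, mild = 0L,
                                     moderate = 0L, severe = 1L),
                           duration = c(0.05, 0.06))
  co <- generate_cohort(cfg)
  ww <- preprocess_recording(co[[1]], normalize = "window")
  for (w in ww[1:3]) {
    expect_equal(min(w$samples), 0)
    expect_equal(max(w$samples), 1)
  }
})
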