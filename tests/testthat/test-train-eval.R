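test_that("balanced class weights equalize the class masses", {
  y <- c(rep(1, 50), rep(0, 50))
  w <- class_weights(y)
  expect_equal(w$weight_pos, 1)
  expect_equal(w$weight_neg, 1)

  # positive fraction 0.145 (apnea:normal ratio ~0.17)
  y <- c(rep(1, 145), rep(0, 855))
  w <- class_weights(y)
  expect_equal(w$weight_pos, 1000 / (2 * 145))  # ~3.448
  expect_equal(w$weight_neg, 1000 / (2 * 855))  # ~0.585
  expect_equal(w$weight_pos * 145, w$weight_neg * 855)

  expect_error(class_weights(rep(1, 10)), "both classes")
})

test_that("the learning-rate schedule is constant then exponentially decayed", {
  tc <- train_config()
  expect_identical(lr_schedule(5, tc), 1e-3)
  expect_identical(lr_schedule(10, tc), 1e-3)
  expect_equal(lr_schedule(11, tc), 9e-4)
  expect_equal(lr_schedule(12, tc), 8.1e-4)
  # the floor binds eventually
  expect_equal(lr_schedule(60, tc), 1e-4)
  trace <- vapply(1:40, lr_schedule, numeric(1), config = tc)
  expect_true(all(diff(trace[10:40]) <= 0))
  expect_true(all(trace >= 1e-4))
})

test_that("weighted cross-entropy with unit weights is the plain loss", {
  set.seed(1)
  z <- matrix(stats::rnorm(60, sd = 3), 6, 10)
  y <- matrix(stats::rbinom(60, 1, 0.3), 6, 10)
  lw <- weighted_bce(z, y, list(weight_pos = 1, weight_neg = 1))
  p <- 1 / (1 + exp(-z))
  plain <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(lw$loss, plain, tolerance = 1e-12)
  # gradient points from probability toward the label
  expect_equal(lw$dlogits, (p - y) / 60, tolerance = 1e-12)
})

test_that("patient-level splits and folds never leak subjects", {
  ids <- sprintf("S%02d", 1:30)
  plan <- split_patients(ids, 0.2, seed = 5)
  expect_length(plan$dev, 24L)
  expect_length(plan$test, 6L)
  expect_length(intersect(plan$dev, plan$test), 0L)
  expect_identical(plan, split_patients(ids, 0.2, seed = 5))
  expect_error(split_patients(ids[1:3]), "at least 5")

  folds <- make_folds(plan$dev, k = 5, seed = 5)
  vals <- lapply(folds, `[[`, "val")
  expect_setequal(unlist(vals), plan$dev)
  expect_identical(anyDuplicated(unlist(vals)), 0L)
  for (f in folds) {
    expect_length(intersect(f$train, f$val), 0L)
    expect_setequal(c(f$train, f$val), plan$dev)
  }

  lit <- make_folds(ids, k = 5, seed = 5, mode = "literal_23_7")
  for (f in lit) {
    expect_length(f$train, 23L)
    expect_length(f$val, 7L)
    expect_length(intersect(f$train, f$val), 0L)
  }

  expect_identical(make_folds(ids[1:25], k = 5, seed = 1) |>
                     lapply(function(f) length(f$val)) |> unlist(),
                   rep(5L, 5))
  expect_error(make_folds(ids, k = 1), "at least 2")
})

test_that("confusion counts match brute-force enumeration", {
  pred <- c(1, 1, 0, 0, 1, 0, 1, 1, 0, 0)
  true <- c(1, 0, 0, 0, 1, 1, 1, 0, 0, 1)
  cc <- confusion(pred, true)
  expect_identical(cc$tp, 3L)
  expect_identical(cc$fp, 2L)
  expect_identical(cc$fn, 2L)
  expect_identical(cc$tn, 3L)
  expect_identical(cc$tp + cc$fp + cc$fn + cc$tn, 10L)

  cc2 <- confusion(true, true)
  expect_identical(cc2$fp + cc2$fn, 0L)
  expect_error(confusion(1:3, 1:4), "lengths")
})

test_that("metric formulas agree with direct computation on expanded labels", {
  m <- compute_metrics(structure(list(tp = 3L, fp = 1L, fn = 2L, tn = 4L),
                                 class = "confusion_counts"))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f1, 2 / 3, tolerance = 1e-12)

  # oracle: reconstruct the label vectors and use base-R arithmetic
  set.seed(2)
  for (i in 1:200) {
    tb <- sample(0:20, 4, replace = TRUE)
    if (sum(tb) == 0) next
    pred <- rep(c(1, 1, 0, 0), tb)
    true <- rep(c(1, 0, 1, 0), tb)
    got <- suppressWarnings(compute_metrics(confusion(pred, true)))
    expect_equal(got$accuracy, mean(pred == true))
    if (sum(true) > 0)
      expect_equal(got$sensitivity, sum(pred & true) / sum(true))
    if (sum(!true) > 0)
      expect_equal(got$specificity, sum(!pred & !true) / sum(!true))
    if (sum(pred) > 0)
      expect_equal(got$precision, sum(pred & true) / sum(pred))
  }

  # zero denominators surface as NaN with warnings, never silent zero
  w <- capture_warnings(m0 <- compute_metrics(structure(
    list(tp = 0L, fp = 0L, fn = 0L, tn = 5L), class = "confusion_counts")))
  expect_true(any(grepl("undefined", w)))
  expect_true(is.nan(m0$sensitivity))
  expect_true(is.nan(m0$precision))
})

test_that("trapezoidal AUC matches pROC and behaves at the extremes", {
  prob <- c(0.9, 0.8, 0.7, 0.2, 0.1)
  y <- c(1, 1, 1, 0, 0)
  expect_equal(roc_auc(prob, y), 1)

  set.seed(3)
  p <- stats::runif(300)
  yy <- stats::rbinom(300, 1, 0.3)
  expect_equal(roc_auc(p, yy),
               as.numeric(pROC::auc(pROC::roc(yy, p, quiet = TRUE))),
               tolerance = 1e-10)
  # with tied probabilities too
  pt <- round(p, 1)
  expect_equal(roc_auc(pt, yy),
               as.numeric(pROC::auc(pROC::roc(yy, pt, quiet = TRUE))),
               tolerance = 1e-10)

  # labels independent of probabilities: AUC near 1/2
  set.seed(4)
  p2 <- stats::runif(20000)
  y2 <- stats::rbinom(20000, 1, 0.145)
  expect_lt(abs(roc_auc(p2, y2) - 0.5), 0.03)
  expect_warning(a <- roc_auc(c(0.2, 0.4), c(1, 1)), "one class")
  expect_true(is.nan(a))
})

test_that("event aggregation and matching follow run-length and overlap rules", {
  ev <- aggregate_events(c(0, 1, 1, 1, 0, 0, 1, 0))
  expect_equal(ev$start, c(1, 6))
  expect_equal(ev$end, c(4, 7))
  expect_identical(nrow(aggregate_events(rep(0, 10))), 0L)
  expect_identical(nrow(aggregate_events(c(1, 1, 0, 1), min_duration = 2)), 1L)

  # round trip: project(aggregate(mask)) recovers the mask
  set.seed(5)
  for (i in 1:50) {
    mask <- stats::rbinom(60, 1, 0.3)
    ev <- aggregate_events(mask)
    expect_identical(project_event_labels(ev, 60), as.integer(mask))
  }

  expect_identical(match_events(data.frame(start = 5, end = 20),
                                data.frame(start = 10, end = 25))$matched, 1L)
  dis <- match_events(data.frame(start = 0, end = 5),
                      data.frame(start = 10, end = 15))
  expect_identical(dis$matched, 0L)
  expect_identical(dis$missed, 1L)
  expect_identical(dis$spurious, 1L)
  same <- data.frame(start = c(0, 30), end = c(12, 45))
  eq <- match_events(same, same)
  expect_identical(eq$missed + eq$spurious, 0L)
  # a detected event is consumed by at most one annotated event
  one_det <- match_events(data.frame(start = 0, end = 50),
                          data.frame(start = c(0, 30), end = c(12, 45)))
  expect_identical(one_det$matched, 1L)
  expect_identical(one_det$missed, 1L)
})

test_that("training refuses degenerate inputs and respects zero epochs", {
  tr <- make_amplitude_dataset(12, seed = 7)
  mc <- model_config(num_blocks = 1L, num_heads = 1L, head_size = 4L,
                     ff_hidden = 8L, mlp_units = 8L, dropout = 0,
                     d_model = 4L, posenc = posenc_config("none"))
  model <- build_classifier(mc, 240L, seed = 8)
  out0 <- train_classifier(model, tr, train_config(epochs = 0L))
  expect_identical(out0$model$params, model$params)
  expect_identical(nrow(out0$history), 0L)

  tr_bad <- tr
  tr_bad$y[] <- 0L
  expect_error(train_classifier(model, tr_bad, train_config(epochs = 1L)),
               "single class")
})

test_that("the pretrained autoencoder mode freezes its weights during training", {
  tr <- make_amplitude_dataset(24, seed = 9)
  pc <- posenc_config("autoencoder", ae_filters = c(4L, 3L),
                      ae_training_mode = "pretrained",
                      ae_pretrain_epochs = 1L)
  mc <- model_config(num_blocks = 1L, num_heads = 1L, head_size = 4L,
                     ff_hidden = 8L, mlp_units = 8L, dropout = 0,
                     d_model = 4L, posenc = pc)
  model <- build_classifier(mc, 240L, seed = 10)
  fit <- train_classifier(model, tr, train_config(epochs = 2L, seed = 10))
  # classifier weights moved; a second identical call reproduces them
  expect_false(identical(fit$model$params$head, model$params$head))
  fit2 <- train_classifier(model, tr, train_config(epochs = 2L, seed = 10))
  expect_identical(fit$model$params, fit2$model$params)
})
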