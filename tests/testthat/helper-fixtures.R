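# Shared fixtures: all synthetic, built in code at test time.

# A short-recording cohort configuration for fast structural tests.
tiny_synth_config <- function(seed = 1L, n_subjects = 4L,
                              quota = c(none = 1L, mild = 1L,
                                        moderate = 1L, severe = 1L),
                              fs = 8, duration = c(0.3, 0.4), ...) {
  synthetic_config(n_subjects = n_subjects, severity_quota = quota,
                   duration_range = duration, fs = fs, seed = seed, ...)
}

# The scaled-down learning-study conditions: 6 subjects with OSA (strong
# RR modulation, depth 0.4), half-hour recordings at 8 Hz.
scaled_synth_config <- function(seed) {
  synthetic_config(n_subjects = 6L,
                   severity_quota = c(none = 0L, mild = 2L,
                                      moderate = 2L, severe = 2L),
                   duration_range = c(0.5, 0.6), fs = 8,
                   rr_modulation_depth = 0.4, seed = seed)
}

# The scaled-down classifier: 2 encoder blocks, 2 heads of size 32,
# 16-channel residual stream, compact autoencoder encoding.
scaled_model_config <- function(strategy = "autoencoder") {
  model_config(num_blocks = 2L, num_heads = 2L, head_size = 32L,
               ff_hidden = 64L, mlp_units = 64L, dropout = 0.1,
               d_model = 16L,
               posenc = posenc_config(strategy, ae_filters = c(32L, 16L),
                                      ae_kernel = 7L))
}

# Train the scaled-down model on one seeded cohort and return the held-out
# second-level AUC (patient-level split, 2 of 6 subjects held out).
scaled_run_auc <- function(seed, strategy = "autoencoder", epochs = 10L) {
  ds <- preprocess_cohort(generate_cohort(scaled_synth_config(seed)))
  plan <- split_patients(unique(ds$subject), 1 / 3, seed = seed)
  dev <- dataset_subset(ds, which(ds$subject %in% plan$dev))
  test <- dataset_subset(ds, which(ds$subject %in% plan$test))
  model <- build_classifier(scaled_model_config(strategy), 240L, seed = seed)
  fit <- train_classifier(model, dev, train_config(epochs = epochs,
                                                   seed = seed))
  pr <- predict_seconds(fit$model, test)
  roc_auc(pr$prob, test$y)
}

# Toy task for the learning sanity check: positive seconds coincide with an
# injected high-amplitude modulated span; everything else is low-level
# noise. Returns a dataset-shaped list.
make_amplitude_dataset <- function(n, fs = 8L, seed = 1L, amp = 1.2) {
  L <- 30L * fs
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * L, 0, 0.2), n, L)
    y <- matrix(0L, n, 30L)
    for (i in seq_len(n)) {
      if (stats::runif(1) < 0.55) {
        len <- sample(10:20, 1)
        s0 <- sample(0:(30 - len), 1)
        sm <- (s0 * fs + 1):((s0 + len) * fs)
        tt <- seq_along(sm) / fs
        X[i, sm] <- X[i, sm] + amp + 0.5 * sin(2 * pi * 2 * tt)
        y[i, (s0 + 1):(s0 + len)] <- 1L
      }
    }
    list(X = X, y = y)
  })
}

# Random non-overlapping event sets for label-projection properties.
random_event_set <- function(duration) {
  n <- sample(0:5, 1)
  if (n == 0)
    return(data.frame(start = numeric(0), end = numeric(0)))
  durs <- stats::runif(n, 10, 30)
  while (sum(durs) > 0.8 * duration) durs <- durs[-length(durs)]
  n <- length(durs)
  if (n == 0)
    return(data.frame(start = numeric(0), end = numeric(0)))
  u <- stats::runif(n + 1)
  gaps <- (duration - sum(durs)) * u / sum(u)
  starts <- cumsum(gaps[seq_len(n)]) + c(0, cumsum(durs))[seq_len(n)]
  data.frame(start = starts, end = starts + durs)
}

# Independent per-second membership oracle: second s is positive iff its
# bin start time lies inside some half-open event interval.
oracle_label_grid <- function(events, duration) {
  n_sec <- floor(duration)
  vapply(seq_len(n_sec) - 1, function(s) {
    any(events$start <= s & s < events$end)
  }, logical(1)) * 1L
}
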