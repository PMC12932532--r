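test_that("RR series holds its baseline and modulates inside events", {
  cfg <- synthetic_config(rr_jitter = 0)

  # single 30-s event: modulation envelope reaches baseline * (1 +/- depth)
  ev <- data.frame(start = 100, end = 130, kind = "apnea")
  set.seed(1)
  rr <- simulate_rr_series(300, cfg, ev)
  t_beat <- cumsum(c(0, rr[-length(rr)]))
  inside <- t_beat >= 100 & t_beat < 130
  expect_equal(max(rr[inside]), 0.9 * 1.25, tolerance = 0.02)
  expect_equal(min(rr[inside]), 0.9 * 0.75, tolerance = 0.02)
  # outside events the interval is exactly the baseline (no jitter here)
  expect_true(all(abs(rr[!inside] - 0.9) < 1e-12))
  # cumulative beats cover the recording
  expect_gte(sum(rr), 300)

  # zero depth: beats inside and outside events are indistinguishable
  cfg0 <- synthetic_config(rr_modulation_depth = 0, rr_jitter = 0.03)
  set.seed(2)
  rr0 <- simulate_rr_series(600, cfg0, ev)
  t0 <- cumsum(c(0, rr0[-length(rr0)]))
  ins0 <- t0 >= 100 & t0 < 130
  expect_equal(mean(rr0[ins0]), mean(rr0[!ins0]), tolerance = 0.02)

  # Monte-Carlo event-free mean: 0.9 within a few standard errors
  set.seed(3)
  rr_free <- simulate_rr_series(3600, synthetic_config(rr_jitter = 0.03))
  expect_gt(length(rr_free), 1000)
  se <- stats::sd(rr_free) / sqrt(length(rr_free))
  expect_lt(abs(mean(rr_free) - 0.9), 5 * se)

  expect_error(simulate_rr_series(100, synthetic_config(),
                                  data.frame(start = 50, end = 150)),
               "within")
  bad <- synthetic_config()
  bad$rr_baseline <- -1
  expect_error(simulate_rr_series(100, bad), "rr_baseline")
})

test_that("ECG synthesis places beat peaks on the RR grid with calibrated noise", {
  # constant RR of 1 s at 80 Hz, no noise: peaks every 80 samples
  x <- synthesize_ecg(rep(1, 10), fs = 80, noise_sd = 0)
  expect_length(x, 800)
  peak_idx <- which(diff(sign(diff(x))) == -2) + 1
  expect_equal(peak_idx, seq(81, 800, by = 80)[seq_along(peak_idx)])

  # round trip: peaks detected from a clean synthesis land within one
  # sample of the cumulative RR times, and re-synthesis from those detected
  # times reproduces the same peak grid
  set.seed(4)
  rr <- runif(20, 0.7, 1.1)
  x1 <- synthesize_ecg(rr, fs = 40, noise_sd = 0)
  peaks <- which(diff(sign(diff(x1))) == -2) + 1
  beat_samples <- round(cumsum(rr) * 40) + 1
  # the final beat falls on the signal's last sample, invisible to a
  # local-maximum detector
  expect_gte(length(peaks), length(rr) - 1L)
  expect_true(all(abs(peaks - beat_samples[seq_along(peaks)]) <= 1))
  rr_hat <- diff(c(0, (peaks - 1) / 40))
  x2 <- synthesize_ecg(rr_hat, fs = 40, noise_sd = 0)
  peaks2 <- which(diff(sign(diff(x2))) == -2) + 1
  # the final beat sits on the last sample of the re-synthesis, where a
  # local-maximum detector cannot see it
  expect_gte(length(peaks2), length(peaks) - 1L)
  expect_identical(peaks2, peaks[seq_along(peaks2)])

  # additive noise SD matches noise_sd (relative to unit peak amplitude)
  set.seed(5)
  xn <- synthesize_ecg(rep(2, 200), fs = 40, noise_sd = 0.05)
  frac <- ((seq_along(xn) - 1) / 40) %% 2
  base <- xn[frac > 0.5 & frac < 1.5]  # inter-beat baseline, far from pulses
  expect_equal(stats::sd(base), 0.05, tolerance = 0.005)

  expect_error(synthesize_ecg(numeric(0), 80), "non-empty")
  expect_error(synthesize_ecg(c(1, -1), 80), "positive")
})

test_that("event placement delivers the target count without overlap", {
  cfg <- synthetic_config()
  set.seed(6)
  expect_identical(nrow(place_events(7 * 3600, 0, cfg)), 0L)
  ev <- place_events(7 * 3600, 3, cfg)
  expect_identical(nrow(ev), 21L)

  for (i in 1:25) {
    ev <- place_events(2 * 3600, runif(1, 1, 50), cfg)
    if (nrow(ev) < 2) next
    expect_true(all(ev$end - ev$start >= 10))
    expect_true(all(ev$start >= 0 & ev$end <= 2 * 3600))
    o <- order(ev$start)
    expect_true(all(ev$start[o][-1] >= ev$end[o][-nrow(ev)]))
  }

  # requested event time beyond 90% of the recording is infeasible
  expect_error(place_events(600, 130 * 6, cfg), "infeasible")
})

test_that("corruption replaces the right fraction and only touches samples", {
  x <- stats::rnorm(1e6)
  expect_identical(corrupt_signal(x, 0), x)
  set.seed(7)
  xc <- corrupt_signal(x, 0.002)
  n_na <- sum(is.na(xc))
  # binomial: 2000 +/- 4.5 sd
  expect_lt(abs(n_na - 2000), 4.5 * sqrt(1e6 * 0.002 * 0.998))
  expect_identical(xc[!is.na(xc)], x[!is.na(xc)])
  expect_error(corrupt_signal(x, 1), "nan_rate")
})

test_that("cohorts are deterministic with exact quotas and in-class AHI", {
  cfg <- tiny_synth_config(seed = 11L)
  co1 <- generate_cohort(cfg, signal = FALSE)
  co2 <- generate_cohort(cfg, signal = FALSE)
  expect_length(co1, 4L)
  expect_identical(lapply(co1, `[[`, "events"), lapply(co2, `[[`, "events"))

  sev <- vapply(co1, `[[`, character(1), "severity")
  expect_identical(table(factor(sev, c("none", "mild", "moderate", "severe"))),
                   table(factor(rep(c("none", "mild", "moderate", "severe")),
                                c("none", "mild", "moderate", "severe"))))
  for (rec in co1) {
    rng <- cfg$ahi_range[[rec$severity]]
    expect_gte(rec$ahi, rng[1])
    expect_lt(rec$ahi, rng[2])
    expect_equal(rec$ahi, nrow(rec$events) / (rec$duration / 3600))
  }

  # waveform rendering does not perturb annotations
  co3 <- generate_cohort(cfg, signal = TRUE)
  expect_identical(lapply(co1, `[[`, "events"), lapply(co3, `[[`, "events"))
  expect_identical(length(co3[[1]]$samples),
                   as.integer(round(co3[[1]]$duration * cfg$fs)))

  bad <- tiny_synth_config()
  bad$severity_quota["none"] <- 2L
  expect_error(generate_cohort(bad), "sum")
})

test_that("event durations follow the truncated lognormal with mean 26 s", {
  cfg <- synthetic_config()
  set.seed(8)
  d <- sample_event_durations(20000, cfg)
  expect_true(all(d >= 10))
  expect_equal(mean(d), 26, tolerance = 0.02)
})
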