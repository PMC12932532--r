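# Synthetic overnight-ECG cohort generator.
#
# Apnea leaves a well-described fingerprint in the ECG: a cyclic pattern of
# bradycardia during the obstruction followed by tachycardia at its
# resolution. The generator reproduces exactly that modulation structure --
# an RR-interval series with a sinusoidal excursion across each event span --
# rendered as a beat-shaped pulse train with additive noise and missing
# samples. Waveform morphology is deliberately schematic (a Gaussian pulse
# per beat): the classifier must not depend on a QRS template, only on the
# modulation structure.

#' Sample truncated-lognormal event durations
#'
#' Durations are lognormal, rejected below the clinical minimum event
#' duration. With the default log-scale parameters the truncated mean is
#' about 26 s.
#'
#' @param n number of durations.
#' @param config a [synthetic_config()].
#' @return numeric vector of durations in seconds, all `>= config$event_min`.
#' @keywords internal
sample_event_durations <- function(n, config) {
  if (n == 0L) return(numeric(0))
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rlnorm(n, config$event_meanlog, config$event_sdlog)
    out <- c(out, d[d >= config$event_min])
  }
  out[seq_len(n)]
}

#' Place non-overlapping apnea/hypopnea events in a recording
#'
#' Draws `round(target_ahi * duration_hours)` event durations from the
#' truncated-lognormal distribution and places them without overlap by
#' distributing the remaining free time into random inter-event gaps
#' (uniform spacings), so non-overlap holds by construction. Event kinds are
#' drawn 2:1 hypopnea:apnea; both kinds map to positive labels downstream.
#'
#' @param duration recording duration in seconds.
#' @param target_ahi target apnea-hypopnea index in events per hour.
#' @param config a [synthetic_config()].
#' @return a data frame with columns `start`, `end` (seconds, half-open
#'   `[start, end)`) and `kind` (`"apnea"` or `"hypopnea"`), ordered by
#'   `start`.
#' @export
place_events <- function(duration, target_ahi, config = synthetic_config()) {
  if (duration <= 0) stop("duration must be positive")
  if (target_ahi < 0) stop("target_ahi must be non-negative")
  n <- round(target_ahi * duration / 3600)
  if (n == 0L)
    return(data.frame(start = numeric(0), end = numeric(0),
                      kind = character(0)))
  durs <- sample_event_durations(n, config)
  if (sum(durs) > 0.9 * duration)
    stop("infeasible event packing: requested event time exceeds 90% of the recording")
  free <- duration - sum(durs)
  u <- stats::runif(n + 1L)
  gaps <- free * u / sum(u)
  starts <- cumsum(gaps[seq_len(n)]) + c(0, cumsum(durs))[seq_len(n)]
  kind <- ifelse(stats::runif(n) < 1 / 3, "apnea", "hypopnea")
  data.frame(start = starts, end = starts + durs, kind = kind)
}

#' Simulate an RR-interval series with apnea modulation
#'
#' Outside events the RR interval fluctuates around `rr_baseline` with small
#' multiplicative Gaussian jitter. Within each event the interval is
#' modulated sinusoidally over the event span by `rr_modulation_depth`:
#' one full cycle of slowing (bradycardia) followed by acceleration
#' (tachycardia). Beats are generated until their cumulative sum covers
#' `duration`.
#'
#' @param duration recording duration in seconds.
#' @param config a [synthetic_config()].
#' @param events event data frame as returned by [place_events()].
#' @return numeric vector of RR intervals in seconds; `sum()` covers
#'   `duration`.
#' @export
simulate_rr_series <- function(duration, config = synthetic_config(),
                               events = NULL) {
  if (duration <= 0) stop("duration must be positive")
  if (config$rr_baseline <= 0) stop("invalid config: rr_baseline must be positive")
  if (is.null(events))
    events <- data.frame(start = numeric(0), end = numeric(0))
  if (nrow(events) > 0 && (min(events$start) < 0 || max(events$end) > duration))
    stop("events must lie within [0, duration]")
  cap <- ceiling(duration / config$rr_baseline * 1.5) + 16L
  jitter <- stats::rnorm(cap, 0, config$rr_jitter)
  rr <- numeric(cap)
  ev_start <- events$start
  ev_end <- events$end
  t <- 0
  i <- 0L
  while (t < duration) {
    i <- i + 1L
    if (i > length(jitter)) jitter <- c(jitter, stats::rnorm(cap, 0, config$rr_jitter))
    if (i > length(rr)) rr <- c(rr, numeric(cap))
    mod <- 1
    if (length(ev_start)) {
      k <- which(ev_start <= t & t < ev_end)
      if (length(k)) {
        k <- k[1L]
        phase <- (t - ev_start[k]) / (ev_end[k] - ev_start[k])
        mod <- 1 + config$rr_modulation_depth * sin(2 * pi * phase)
      }
    }
    rr[i] <- config$rr_baseline * mod * (1 + jitter[i])
    t <- t + rr[i]
  }
  rr[seq_len(i)]
}

#' Render an RR-interval series as an ECG-like pulse train
#'
#' Each beat is a unit-amplitude Gaussian pulse centered at the cumulative
#' RR time; Gaussian noise with standard deviation `noise_sd` (a fraction of
#' the peak amplitude) is added to every sample. The waveform model is
#' intentionally schematic and replaceable.
#'
#' @param rr_series positive RR intervals in seconds.
#' @param fs sampling frequency in Hz.
#' @param noise_sd additive noise SD as a fraction of the peak amplitude.
#' @param pulse_width Gaussian pulse standard deviation in seconds.
#' @return numeric amplitude vector of length `round(sum(rr_series) * fs)`.
#' @export
synthesize_ecg <- function(rr_series, fs, noise_sd = 0.05,
                           pulse_width = 0.05) {
  if (length(rr_series) == 0L) stop("rr_series must be non-empty")
  if (any(rr_series <= 0)) stop("all RR intervals must be positive")
  if (fs <= 0) stop("fs must be positive")
  beat_times <- cumsum(rr_series)
  n <- round(sum(rr_series) * fs)
  x <- numeric(n)
  half <- 4 * pulse_width
  for (b in beat_times) {
    lo <- max(1L, floor((b - half) * fs) + 1L)
    hi <- min(n, ceiling((b + half) * fs) + 1L)
    if (lo > hi) next
    tt <- (seq(lo, hi) - 1L) / fs
    seg <- exp(-((tt - b)^2) / (2 * pulse_width^2))
    x[lo:hi] <- x[lo:hi] + seg
  }
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  x
}

#' Replace a random fraction of samples with missing markers
#'
#' Each sample is independently replaced by `NA` with probability
#' `nan_rate`; all other samples are untouched. Annotations are never
#' affected by corruption.
#'
#' @param samples numeric amplitude vector.
#' @param nan_rate missing-sample probability in `[0, 1)`.
#' @return `samples` with `NA` at the corrupted positions.
#' @export
corrupt_signal <- function(samples, nan_rate) {
  if (nan_rate < 0 || nan_rate >= 1) stop("nan_rate must be in [0, 1)")
  if (nan_rate == 0) return(samples)
  samples[stats::runif(length(samples)) < nan_rate] <- NA_real_
  samples
}

#' Apnea-hypopnea index of a recording
#'
#' @param recording an `apnea_recording`.
#' @return events per hour: `nrow(events) / duration_hours`.
#' @export
compute_ahi <- function(recording) {
  nrow(recording$events) / (recording$duration / 3600)
}

# Draw a target AHI inside the class interval that the recording duration
# can actually realize: event counts are integers, so the achieved AHI is
# n / hours. Sampling uniformly over the feasible counts keeps the class
# mean at the interval midpoint for overnight durations while staying exact
# for short recordings.
draw_target_ahi <- function(class_range, duration) {
  hours <- duration / 3600
  counts <- ceiling(class_range[1] * hours):floor(class_range[2] * hours)
  counts <- counts[counts / hours >= class_range[1] &
                   counts / hours < class_range[2]]
  if (!length(counts))
    stop("recording too short to realize an AHI in [",
         class_range[1], ", ", class_range[2], ")")
  if (length(counts) == 1L) return(counts / hours)
  sample(counts, 1L) / hours
}

#' Generate one synthetic annotated recording
#'
#' @param subject_id subject identifier.
#' @param duration duration in seconds.
#' @param severity AHI class: `"none"`, `"mild"`, `"moderate"`, `"severe"`.
#' @param config a [synthetic_config()].
#' @param seeds integer vector of 3 sub-seeds (events, signal, corruption);
#'   using separate streams keeps annotations identical whether or not the
#'   waveform is rendered.
#' @param signal if `FALSE`, skip waveform synthesis (annotation-only mode
#'   for cohort-level statistics); `samples` is then `NULL`.
#' @return an `apnea_recording`: list with `subject_id`, `fs`, `samples`,
#'   `events`, `duration` (s), `severity`, `ahi`.
#' @export
generate_recording <- function(subject_id, duration, severity,
                               config = synthetic_config(),
                               seeds = c(1L, 2L, 3L), signal = TRUE) {
  class_range <- config$ahi_range[[severity]]
  events <- withr::with_seed(seeds[1], {
    ahi <- draw_target_ahi(class_range, duration)
    place_events(duration, ahi, config)
  })
  samples <- NULL
  if (signal) {
    samples <- withr::with_seed(seeds[2], {
      rr <- simulate_rr_series(duration, config, events)
      synthesize_ecg(rr, config$fs, config$noise_sd)
    })
    # The beat train overshoots `duration` by up to one RR interval; trim so
    # the recording length (and hence the AHI denominator) stays as drawn.
    samples <- samples[seq_len(min(length(samples), round(duration * config$fs)))]
    samples <- withr::with_seed(seeds[3],
                                corrupt_signal(samples, config$nan_rate))
    duration <- length(samples) / config$fs
  }
  rec <- structure(list(subject_id = subject_id,
                        fs = config$fs,
                        samples = samples,
                        events = events,
                        duration = duration,
                        severity = severity,
                        ahi = NA_real_),
                   class = "apnea_recording")
  rec$ahi <- compute_ahi(rec)
  rec
}

#' Generate a seeded synthetic cohort
#'
#' Produces `config$n_subjects` annotated recordings with severity-class
#' counts exactly equal to `config$severity_quota` and each subject's AHI
#' inside its class interval. The cohort is a deterministic function of
#' `(config, config$seed)`; per-subject sub-seeds keep annotations
#' byte-identical between `signal = TRUE` and `signal = FALSE` runs.
#'
#' @param config a [synthetic_config()].
#' @param signal render waveforms (`TRUE`) or annotations only (`FALSE`).
#' @return a list of `apnea_recording` objects with attribute `config`.
#' @export
generate_cohort <- function(config = synthetic_config(), signal = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_subjects
  if (sum(config$severity_quota) != n)
    stop("invalid config: severity_quota must sum to n_subjects")
  plan <- withr::with_seed(config$seed, {
    list(seeds = matrix(sample.int(.Machine$integer.max, 3L * n), ncol = 3L),
         durations = stats::runif(n, config$duration_range[1],
                                  config$duration_range[2]) * 3600)
  })
  severity <- rep(names(config$severity_quota), times = config$severity_quota)
  ids <- sprintf("S%02d", seq_len(n))
  cohort <- lapply(seq_len(n), function(i) {
    generate_recording(ids[i], plan$durations[i], severity[i], config,
                       seeds = plan$seeds[i, ], signal = signal)
  })
  attr(cohort, "config") <- config
  cohort
}

#' @export
print.apnea_recording <- function(x, ...) {
  cat(sprintf("<apnea_recording> %s: %.2f h at %g Hz, %d events (AHI %.1f, %s)%s\n",
              x$subject_id, x$duration / 3600, x$fs, nrow(x$events), x$ahi,
              x$severity,
              if (is.null(x$samples)) " [annotations only]" else ""))
  invisible(x)
}
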