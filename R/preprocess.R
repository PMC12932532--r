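# Preprocessing: normalization, imputation, windowing, label projection.
#
# Order of operations matters and is fixed: the min and max are computed
# over the non-missing samples of the whole array first, missing values are
# set to zero afterwards (imputing first would corrupt the minimum), and
# segmentation happens last.

#' Min-max normalize a signal to [0, 1]
#'
#' `(x - min) / (max - min)` computed over the non-missing values; missing
#' values are subsequently set to 0 by [impute_missing()] in the standard
#' chain. A constant (degenerate-range) input maps entirely to 0.
#'
#' @param samples numeric vector, possibly containing `NA`.
#' @return vector of the same length with non-missing values in `[0, 1]`
#'   (missing values are preserved; impute separately).
#' @export
normalize_minmax <- function(samples) {
  v <- samples[!is.na(samples)]
  if (length(v) == 0L) stop("cannot normalize an all-missing signal")
  lo <- min(v)
  hi <- max(v)
  if (hi == lo) {
    samples[!is.na(samples)] <- 0
    return(samples)
  }
  (samples - lo) / (hi - lo)
}

#' Replace missing samples by zero
#'
#' @param samples numeric vector.
#' @return `samples` with every `NA` replaced by 0.
#' @export
impute_missing <- function(samples) {
  samples[is.na(samples)] <- 0
  samples
}

#' Project event annotations onto a one-second label grid
#'
#' Second `s` (0-based) is positive iff its bin start time `t = s` lies in
#' some half-open event interval `[start, end)`. Positives therefore form
#' contiguous runs that preserve the event duration in whole seconds, and no
#' isolated positives appear outside annotated events.
#'
#' @param events data frame with `start`, `end` columns in seconds.
#' @param duration recording duration in seconds; the grid has
#'   `floor(duration)` bins.
#' @return integer 0/1 vector of length `floor(duration)`.
#' @export
project_event_labels <- function(events, duration) {
  n_sec <- floor(duration)
  grid <- integer(n_sec)
  if (is.null(events) || nrow(events) == 0L) return(grid)
  if (any(events$start < 0) || any(events$end > duration) ||
      any(events$start >= events$end))
    stop("event outside recording or empty interval")
  for (i in seq_len(nrow(events))) {
    s0 <- ceiling(events$start[i])
    s1 <- min(ceiling(events$end[i]) - 1, n_sec - 1L)
    if (s0 <= s1) grid[(s0 + 1L):(s1 + 1L)] <- 1L
  }
  grid
}

#' Segment a recording into non-overlapping windows
#'
#' Window `k` (0-based) covers `[window_s * k, window_s * (k + 1))` seconds;
#' the trailing partial window is dropped. Each window carries one binary
#' label per second, obtained from [project_event_labels()]; an event
#' spanning a window boundary contributes positives to both windows.
#'
#' @param recording an `apnea_recording` whose `samples` have already been
#'   normalized and imputed (use [preprocess_recording()] for the full
#'   chain).
#' @param window_s window length in seconds.
#' @return list of `apnea_window` objects: `subject_id`, `window_index`
#'   (0-based), `samples` (length `window_s * fs`), `labels` (length
#'   `window_s`), `start_time` (s).
#' @export
segment_windows <- function(recording, window_s = 30L) {
  if (is.null(recording$samples))
    stop("recording has no samples (annotation-only recording)")
  fs <- recording$fs
  duration <- length(recording$samples) / fs
  n_win <- floor(duration / window_s)
  if (n_win == 0L) return(list())
  grid <- project_event_labels(recording$events, duration)
  spw <- round(window_s * fs)
  lapply(seq_len(n_win) - 1L, function(k) {
    structure(list(subject_id = recording$subject_id,
                   window_index = k,
                   samples = recording$samples[(k * spw + 1L):((k + 1L) * spw)],
                   labels = grid[(k * window_s + 1L):((k + 1L) * window_s)],
                   start_time = k * window_s),
              class = "apnea_window")
  })
}

#' Preprocess one recording into labeled windows
#'
#' The full chain: min-max normalization (over the non-missing values of
#' the whole recording by default, or per window), missing-value
#' imputation to zero, segmentation into non-overlapping windows, and
#' per-second label projection.
#'
#' @param recording an `apnea_recording`.
#' @param window_s window length in seconds.
#' @param normalize `"recording"` (default) rescales over the whole
#'   recording; `"window"` rescales each window independently.
#' @return list of `apnea_window` objects.
#' @export
preprocess_recording <- function(recording, window_s = 30L,
                                 normalize = c("recording", "window")) {
  normalize <- match.arg(normalize)
  if (is.null(recording$samples))
    stop("recording has no samples (annotation-only recording)")
  if (normalize == "recording") {
    recording$samples <- impute_missing(normalize_minmax(recording$samples))
    segment_windows(recording, window_s)
  } else {
    windows <- segment_windows(recording, window_s)
    lapply(windows, function(w) {
      w$samples <- impute_missing(normalize_minmax(w$samples))
      w
    })
  }
}

#' Assemble windows into a model-ready dataset
#'
#' @param windows list of `apnea_window` objects with a common sampling
#'   frequency (equal sample counts).
#' @param fs sampling frequency in Hz (stored for bookkeeping; inferred
#'   window length must be homogeneous).
#' @return an `apnea_dataset`: list with `X` (array `n x L x 1`), `y`
#'   (matrix `n x seconds`), `subject` (character), `window_index`
#'   (integer), `fs`.
#' @export
windows_to_dataset <- function(windows, fs = NULL) {
  n <- length(windows)
  if (n == 0L) {
    return(structure(list(X = array(numeric(0), c(0L, 0L, 1L)),
                          y = matrix(integer(0), 0L, 0L),
                          subject = character(0),
                          window_index = integer(0),
                          fs = fs),
                     class = "apnea_dataset"))
  }
  lens <- vapply(windows, function(w) length(w$samples), integer(1))
  if (length(unique(lens)) != 1L)
    stop("windows have mixed sequence lengths")
  L <- lens[1]
  S <- length(windows[[1]]$labels)
  X <- array(0, c(n, L, 1L))
  y <- matrix(0L, n, S)
  for (i in seq_len(n)) {
    X[i, , 1L] <- windows[[i]]$samples
    y[i, ] <- windows[[i]]$labels
  }
  structure(list(X = X, y = y,
                 subject = vapply(windows, function(w) w$subject_id, character(1)),
                 window_index = vapply(windows, function(w) w$window_index, integer(1)),
                 fs = fs),
            class = "apnea_dataset")
}

#' Preprocess a whole cohort into one dataset
#'
#' @param cohort list of `apnea_recording` objects.
#' @param window_s window length in seconds.
#' @param normalize see [preprocess_recording()].
#' @return an `apnea_dataset` pooling all subjects' windows.
#' @export
preprocess_cohort <- function(cohort, window_s = 30L,
                              normalize = c("recording", "window")) {
  normalize <- match.arg(normalize)
  windows <- unlist(lapply(cohort, preprocess_recording,
                           window_s = window_s, normalize = normalize),
                    recursive = FALSE)
  fs <- if (length(cohort)) cohort[[1]]$fs else NULL
  windows_to_dataset(windows, fs = fs)
}

#' Subset an apnea dataset by window indices
#'
#' @param dataset an `apnea_dataset`.
#' @param idx integer vector of window (row) indices.
#' @return the subsetted `apnea_dataset`.
#' @export
dataset_subset <- function(dataset, idx) {
  structure(list(X = dataset$X[idx, , , drop = FALSE],
                 y = dataset$y[idx, , drop = FALSE],
                 subject = dataset$subject[idx],
                 window_index = dataset$window_index[idx],
                 fs = dataset$fs),
            class = "apnea_dataset")
}

#' @export
print.apnea_dataset <- function(x, ...) {
  cat(sprintf("<apnea_dataset> %d windows x %d samples, %d subjects, %.1f%% positive seconds\n",
              dim(x$X)[1], dim(x$X)[2], length(unique(x$subject)),
              100 * mean(x$y)))
  invisible(x)
}
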