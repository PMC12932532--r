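# Recording and run-artifact I/O. Recordings use a two-CSV convention:
# `<id>_signal.csv` (columns t_s, ecg; missing samples as empty fields) and
# `<id>_events.csv` (columns start_s, end_s, kind).

#' Write a recording to CSV files
#'
#' @param recording an `apnea_recording` with samples.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_recording_csv <- function(recording, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(recording$samples))
    stop("recording has no samples to write")
  sig <- file.path(dir, paste0(recording$subject_id, "_signal.csv"))
  evt <- file.path(dir, paste0(recording$subject_id, "_events.csv"))
  n <- length(recording$samples)
  utils::write.csv(data.frame(t_s = (seq_len(n) - 1) / recording$fs,
                              ecg = recording$samples),
                   sig, row.names = FALSE, na = "")
  utils::write.csv(data.frame(start_s = recording$events$start,
                              end_s = recording$events$end,
                              kind = recording$events$kind),
                   evt, row.names = FALSE)
  invisible(c(signal = sig, events = evt))
}

#' Read a recording from CSV files
#'
#' @param dir directory containing `<subject_id>_signal.csv` and
#'   `<subject_id>_events.csv`.
#' @param subject_id subject identifier.
#' @return an `apnea_recording` (severity unknown: `NA`).
#' @export
read_recording_csv <- function(dir, subject_id) {
  sig <- utils::read.csv(file.path(dir, paste0(subject_id, "_signal.csv")))
  evt <- utils::read.csv(file.path(dir, paste0(subject_id, "_events.csv")),
                         colClasses = c("numeric", "numeric", "character"))
  fs <- 1 / stats::median(diff(sig$t_s))
  rec <- structure(list(subject_id = subject_id,
                        fs = round(fs, 6),
                        samples = sig$ecg,
                        events = data.frame(start = evt$start_s,
                                            end = evt$end_s,
                                            kind = evt$kind),
                        duration = length(sig$ecg) / fs,
                        severity = NA_character_,
                        ahi = NA_real_),
                   class = "apnea_recording")
  rec$ahi <- compute_ahi(rec)
  rec
}

#' Write a metrics report as JSON
#'
#' @param report a `metrics_report`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_metrics_json <- function(report, path) {
  out <- list(accuracy = report$accuracy,
              sensitivity = report$sensitivity,
              specificity = report$specificity,
              precision = report$precision,
              f1 = report$f1,
              auc = report$auc,
              counts = unclass(report$counts),
              event_level = report$event_level)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "string")
  invisible(path)
}
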