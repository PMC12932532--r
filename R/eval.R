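# Second-level and event-level evaluation.

#' Second-level confusion counts
#'
#' @param pred binary predictions (vector or matrix).
#' @param truth matching binary ground truth.
#' @return a `confusion_counts` list with `tp`, `fp`, `fn`, `tn`; the four
#'   counts sum to the number of evaluated seconds.
#' @export
confusion <- function(pred, truth) {
  p <- as.vector(pred)
  t <- as.vector(truth)
  if (length(p) != length(t)) stop("pred and truth lengths differ")
  structure(list(tp = sum(p == 1 & t == 1),
                 fp = sum(p == 1 & t == 0),
                 fn = sum(p == 0 & t == 1),
                 tn = sum(p == 0 & t == 0)),
            class = "confusion_counts")
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the ROC curve swept over the unique predicted
#' probabilities (tied probabilities are grouped, which makes the trapezoid
#' equal the rank statistic).
#'
#' @param prob predicted probabilities.
#' @param truth binary ground truth.
#' @return AUC in `[0, 1]`; `NaN` with a warning if only one class is
#'   present.
#' @export
roc_auc <- function(prob, truth) {
  p <- as.vector(prob)
  y <- as.vector(truth)
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    warning("AUC undefined: only one class present")
    return(NaN)
  }
  ord <- order(p, decreasing = TRUE)
  y <- y[ord]
  p <- p[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  keep <- c(p[-1] != p[-length(p)], TRUE)  # last index of each tied group
  tpr <- c(0, tp[keep] / n_pos)
  fpr <- c(0, fp[keep] / n_neg)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Metrics report from confusion counts
#'
#' Accuracy, sensitivity (recall), specificity, precision and F1 from the
#' 2x2 table, plus trapezoidal ROC-AUC when probabilities are supplied.
#' Ratios with zero denominators are reported as `NaN` with a warning,
#' never silently as 0.
#'
#' @param counts a `confusion_counts`.
#' @param prob optional predicted probabilities (for AUC).
#' @param truth optional ground truth matching `prob`.
#' @return a `metrics_report` list: `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1`, `auc`, `counts`.
#' @export
compute_metrics <- function(counts, prob = NULL, truth = NULL) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  n <- tp + fp + fn + tn
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NaN)
    }
    num / den
  }
  sens <- ratio(tp, tp + fn, "sensitivity")
  prec <- ratio(tp, tp + fp, "precision")
  f1 <- if (is.nan(sens) || is.nan(prec) || sens + prec == 0) {
    warning("F1 undefined")
    NaN
  } else 2 * prec * sens / (prec + sens)
  auc <- if (!is.null(prob)) roc_auc(prob, truth) else NA_real_
  structure(list(accuracy = ratio(tp + tn, n, "accuracy"),
                 sensitivity = sens,
                 specificity = ratio(tn, tn + fp, "specificity"),
                 precision = prec,
                 f1 = f1,
                 auc = auc,
                 counts = counts),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> acc %.4f  sens %.4f  spec %.4f  ",
                     "prec %.4f  F1 %.4f  AUC %s\n"),
              x$accuracy, x$sensitivity, x$specificity, x$precision, x$f1,
              ifelse(is.na(x$auc), "-", sprintf("%.4f", x$auc))))
  invisible(x)
}

#' Aggregate contiguous positive seconds into detected events
#'
#' Maximal runs of consecutive positive seconds become half-open events
#' `[run_start, run_end + 1)`. An optional minimum duration discards short
#' runs (off by default).
#'
#' @param mask binary per-second vector.
#' @param min_duration minimum event duration in seconds (0 = keep all).
#' @return data frame with `start`, `end` columns (seconds).
#' @export
aggregate_events <- function(mask, min_duration = 0) {
  mask <- as.integer(as.vector(mask))
  if (length(mask) == 0L || all(mask == 0L))
    return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pos <- r$values == 1L
  out <- data.frame(start = as.numeric(starts[pos] - 1L),
                    end = as.numeric(ends[pos]))
  out[out$end - out$start >= min_duration, , drop = FALSE]
}

#' Match detected events against annotated events
#'
#' Any-overlap matching: an annotated event is matched if some detected
#' event overlaps it; matching is greedy in start-time order and each
#' event of either set is used at most once. An optional minimum overlap
#' fraction (of the annotated event's duration) tightens the criterion.
#'
#' @param detected data frame with `start`, `end`.
#' @param annotated data frame with `start`, `end`.
#' @param min_overlap_frac minimum overlap as a fraction of the annotated
#'   event duration (0 = any overlap).
#' @return list with `matched`, `missed`, `spurious` counts.
#' @export
match_events <- function(detected, annotated, min_overlap_frac = 0) {
  if (nrow(annotated)) annotated <- annotated[order(annotated$start), ]
  if (nrow(detected)) detected <- detected[order(detected$start), ]
  used <- logical(nrow(detected))
  matched <- 0L
  for (i in seq_len(nrow(annotated))) {
    ov <- pmin(detected$end, annotated$end[i]) -
      pmax(detected$start, annotated$start[i])
    need <- min_overlap_frac * (annotated$end[i] - annotated$start[i])
    hit <- which(!used & ov > 0 & ov >= need)
    if (length(hit)) {
      used[hit[1L]] <- TRUE
      matched <- matched + 1L
    }
  }
  list(matched = matched,
       missed = nrow(annotated) - matched,
       spurious = sum(!used))
}

#' Evaluate a trained classifier on a dataset
#'
#' Runs evaluation-mode prediction, pools all seconds, and reports
#' second-level metrics plus event-level match counts obtained by
#' aggregating each subject's predicted seconds into events and comparing
#' them with events aggregated from the true labels.
#'
#' @param model an `apnea_classifier`.
#' @param dataset an `apnea_dataset`.
#' @param threshold probability threshold for a positive call.
#' @return a `metrics_report` with an `event_level` element.
#' @export
evaluate_classifier <- function(model, dataset, threshold = 0.5) {
  pr <- predict_seconds(model, dataset, threshold = threshold)
  rep <- compute_metrics(confusion(pr$pred, dataset$y),
                         prob = pr$prob, truth = dataset$y)
  ev <- list(matched = 0L, missed = 0L, spurious = 0L)
  for (s in unique(dataset$subject)) {
    idx <- which(dataset$subject == s)
    idx <- idx[order(dataset$window_index[idx])]
    det <- aggregate_events(as.vector(t(pr$pred[idx, , drop = FALSE])))
    ann <- aggregate_events(as.vector(t(dataset$y[idx, , drop = FALSE])))
    m <- match_events(det, ann)
    ev$matched <- ev$matched + m$matched
    ev$missed <- ev$missed + m$missed
    ev$spurious <- ev$spurious + m$spurious
  }
  rep$event_level <- ev
  rep
}
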