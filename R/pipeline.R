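# End-to-end pipeline: simulate -> preprocess -> split -> train ->
# evaluate, driven by one nested run configuration that freezes to YAML so
# every run is reconstructable from its config and seed alone.

#' Assemble a full run configuration
#'
#' @param synthetic a [synthetic_config()].
#' @param model a [model_config()].
#' @param train a [train_config()].
#' @param window_s preprocessing window length in seconds.
#' @param normalize `"recording"` or `"window"` min-max scope.
#' @param test_fraction patient-level held-out fraction.
#' @param threshold prediction threshold.
#' @param seed global seed; stage seeds are derived from it.
#' @return a `run_config` list.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       model = model_config(),
                       train = train_config(),
                       window_s = 30L,
                       normalize = c("recording", "window"),
                       test_fraction = 0.2,
                       threshold = 0.5,
                       seed = 1L) {
  normalize <- match.arg(normalize)
  structure(list(synthetic = synthetic, model = model, train = train,
                 window_s = as.integer(window_s), normalize = normalize,
                 test_fraction = test_fraction, threshold = threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Derive per-stage seeds from the global seed so each stage has its own
# reproducible stream.
derive_seeds <- function(seed) {
  withr::with_seed(seed,
                   stats::setNames(as.list(sample.int(.Machine$integer.max, 4L)),
                                   c("cohort", "split", "init", "train")))
}

#' Serialize a run configuration to YAML
#'
#' @param config a `run_config`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  out <- strip(config)
  # a named atomic vector loses its names in YAML; a named list keeps them
  out$synthetic$severity_quota <- as.list(config$synthetic$severity_quota)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Reconstructs the typed configuration objects (with validation) from a
#' YAML file written by [write_run_config()] or by hand. Missing sections
#' fall back to defaults; unknown keys raise an error naming the key.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(section, fn) {
    args <- raw[[section]]
    if (is.null(args)) return(fn())
    known <- names(formals(fn))
    bad <- setdiff(names(args), known)
    if (length(bad))
      stop("unknown key(s) in '", section, "': ", paste(bad, collapse = ", "))
    if (section == "synthetic" && !is.null(args$severity_quota))
      args$severity_quota <- unlist(args$severity_quota)
    if (section == "model" && !is.null(args$posenc))
      args$posenc <- do.call(posenc_config, args$posenc)
    do.call(fn, args)
  }
  top <- setdiff(names(raw), c("synthetic", "model", "train", "window_s",
                               "normalize", "test_fraction", "threshold",
                               "seed"))
  if (length(top))
    stop("unknown top-level key(s): ", paste(top, collapse = ", "))
  run_config(synthetic = build("synthetic", synthetic_config),
             model = build("model", model_config),
             train = build("train", train_config),
             window_s = raw$window_s %||% 30L,
             normalize = raw$normalize %||% "recording",
             test_fraction = raw$test_fraction %||% 0.2,
             threshold = raw$threshold %||% 0.5,
             seed = raw$seed %||% 1L)
}

log_line <- function(path, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(line)
}

#' Run the full pipeline
#'
#' Simulates a cohort, preprocesses it into windows, splits patients,
#' trains the classifier on the development subjects and evaluates on the
#' held-out subjects. Writes a deterministic directory layout: `cohort/`
#' (recording CSVs), `dataset.rds`, `run.yaml` (frozen config),
#' `metrics.json`, `predictions.csv`, `log.txt`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param resume allow writing into a directory holding a previous partial
#'   run.
#' @param write_cohort write per-recording CSV files (can be large;
#'   default `FALSE`).
#' @return invisibly, a list with `metrics`, `history`, `split`, `model`.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE,
                         write_cohort = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (dir.exists(out_dir) && file.exists(file.path(out_dir, "run.yaml")) &&
      !resume)
    stop("output directory holds a previous run; use resume = TRUE to overwrite")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "log.txt")
  seeds <- derive_seeds(config$seed)
  write_run_config(config, file.path(out_dir, "run.yaml"))

  sconf <- config$synthetic
  sconf$seed <- seeds$cohort
  log_line(logf, "simulate", sprintf("n=%d seed=%d", sconf$n_subjects, sconf$seed))
  cohort <- generate_cohort(sconf)
  if (write_cohort) {
    for (rec in cohort) write_recording_csv(rec, file.path(out_dir, "cohort"))
  }

  log_line(logf, "preprocess", sprintf("window_s=%d normalize=%s",
                                       config$window_s, config$normalize))
  dataset <- preprocess_cohort(cohort, config$window_s, config$normalize)
  saveRDS(dataset, file.path(out_dir, "dataset.rds"))

  plan <- split_patients(unique(dataset$subject), config$test_fraction,
                         seed = seeds$split)
  log_line(logf, "split", sprintf("dev=%d test=%d", length(plan$dev),
                                  length(plan$test)))

  seq_len_model <- round(config$window_s * sconf$fs)
  model <- build_classifier(config$model, seq_len_model, seed = seeds$init)
  tconf <- config$train
  tconf$seed <- seeds$train
  dev_idx <- which(dataset$subject %in% plan$dev)
  log_line(logf, "train", sprintf("windows=%d epochs=%d optimizer=%s",
                                  length(dev_idx), tconf$epochs,
                                  tconf$optimizer))
  fit <- train_classifier(model, dataset_subset(dataset, dev_idx), tconf)
  utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  save_classifier(fit$model, file.path(out_dir, "model.rds"))

  test <- dataset_subset(dataset, which(dataset$subject %in% plan$test))
  metrics <- evaluate_classifier(fit$model, test, config$threshold)
  log_line(logf, "evaluate", sprintf("test windows=%d auc=%.4f",
                                     nrow(test$y), metrics$auc))
  write_metrics_json(metrics, file.path(out_dir, "metrics.json"))

  pr <- predict_seconds(fit$model, test, threshold = config$threshold)
  S <- ncol(test$y)
  preds <- data.frame(
    subject = rep(test$subject, each = S),
    window = rep(test$window_index, each = S),
    second = rep(seq_len(S) - 1L, times = nrow(test$y)),
    prob = as.vector(t(pr$prob)),
    pred = as.vector(t(pr$pred)),
    truth = as.vector(t(test$y)))
  utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  invisible(list(metrics = metrics, history = fit$history, split = plan,
                 model = fit$model))
}

#' Positional-encoding ablation on one shared cohort
#'
#' Trains the five model variants on the same cohort, split and seeds, and
#' tabulates their held-out metrics side by side: no positional encoding
#' with plain Adam (AMSGrad), naive, sinusoidal, no encoding with AdamW
#' weight decay, and the autoencoder encoding with AdamW.
#'
#' @param config a [run_config()]; its `model$posenc` and
#'   `train$optimizer` are overridden per variant. For the sinusoidal
#'   variant (and any variant when `config$model$d_model > 1`) the learned
#'   input embedding width is `config$model$d_model`.
#' @param out_dir optional directory for `ablation.csv`.
#' @return data frame of metrics, one row per variant.
#' @export
run_ablation <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed)
  sconf <- config$synthetic
  sconf$seed <- seeds$cohort
  cohort <- generate_cohort(sconf)
  dataset <- preprocess_cohort(cohort, config$window_s, config$normalize)
  plan <- split_patients(unique(dataset$subject), config$test_fraction,
                         seed = seeds$split)
  dev <- dataset_subset(dataset, which(dataset$subject %in% plan$dev))
  test <- dataset_subset(dataset, which(dataset$subject %in% plan$test))
  variants <- list(
    model_1 = list(strategy = "none", optimizer = "adam_amsgrad"),
    model_2 = list(strategy = "naive", optimizer = "adam_amsgrad"),
    model_3 = list(strategy = "sinusoidal", optimizer = "adam_amsgrad"),
    model_4 = list(strategy = "none", optimizer = "adamw"),
    model_5 = list(strategy = "autoencoder", optimizer = "adamw"))
  seq_len_model <- round(config$window_s * sconf$fs)
  rows <- lapply(names(variants), function(nm) {
    v <- variants[[nm]]
    mconf <- config$model
    mconf$posenc$strategy <- v$strategy
    # the sinusoidal table needs an even channel width to pair sin/cos
    if (v$strategy == "sinusoidal" && mconf$d_model %% 2L != 0L)
      mconf$d_model <- mconf$d_model + 1L
    mconf <- do.call(model_config,
                     c(mconf[setdiff(names(mconf), "posenc")],
                       list(posenc = mconf$posenc)))
    tconf <- config$train
    tconf$optimizer <- v$optimizer
    tconf$seed <- seeds$train
    model <- build_classifier(mconf, seq_len_model, seed = seeds$init)
    fit <- train_classifier(model, dev, tconf)
    m <- evaluate_classifier(fit$model, test, config$threshold)
    data.frame(model = nm, strategy = v$strategy, optimizer = v$optimizer,
               accuracy = m$accuracy, sensitivity = m$sensitivity,
               specificity = m$specificity, precision = m$precision,
               f1 = m$f1, auc = m$auc)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "ablation.csv"),
                     row.names = FALSE)
  }
  out
}
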