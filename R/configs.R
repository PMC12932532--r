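#' Synthetic cohort configuration
#'
#' Parameters of the synthetic overnight-ECG cohort generator. Defaults
#' emulate the structure of a 30-patient clinical polysomnography cohort:
#' 7 subjects without OSA (AHI < 5) and the remainder spread over the
#' conventional mild / moderate / severe AHI classes, recordings of 7--12 h
#' sampled at 80 Hz, respiratory events of at least 10 s with mean duration
#' about 26 s, light additive noise and a small fraction of missing samples.
#' Under these defaults the pooled ratio of apnea-labeled to normal-labeled
#' seconds is approximately 0.17.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param severity_quota named integer vector `c(none, mild, moderate,
#'   severe)` of subject counts per AHI class; must sum to `n_subjects`.
#' @param ahi_range named list of `c(lo, hi)` AHI intervals (events per hour)
#'   per class. The `none` class must lie strictly below 5.
#' @param duration_range recording duration range in hours.
#' @param fs sampling frequency in Hz.
#' @param event_meanlog,event_sdlog log-scale parameters of the lognormal
#'   event-duration distribution, truncated below at `event_min` seconds.
#'   The defaults give a truncated mean of 26 s.
#' @param event_min minimum event duration in seconds.
#' @param rr_baseline baseline RR interval in seconds.
#' @param rr_modulation_depth fractional depth of the cyclic RR modulation
#'   (bradycardia then tachycardia) inside apnea/hypopnea events.
#' @param rr_jitter fractional standard deviation of beat-to-beat RR jitter.
#' @param noise_sd additive Gaussian noise standard deviation as a fraction
#'   of the beat peak amplitude.
#' @param nan_rate expected fraction of samples replaced by missing markers.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   `(config, seed)`.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 30L,
                             severity_quota = c(none = 7L, mild = 8L,
                                                moderate = 8L, severe = 7L),
                             ahi_range = list(none = c(0.5, 4.5),
                                              mild = c(5, 15),
                                              moderate = c(15, 30),
                                              severe = c(30, 60)),
                             duration_range = c(7, 12),
                             fs = 80,
                             event_meanlog = 3.134957,
                             event_sdlog = 0.45,
                             event_min = 10,
                             rr_baseline = 0.9,
                             rr_modulation_depth = 0.25,
                             rr_jitter = 0.03,
                             noise_sd = 0.05,
                             nan_rate = 0.002,
                             seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) stop("n_subjects must be a positive integer")
  classes <- c("none", "mild", "moderate", "severe")
  if (!identical(sort(names(severity_quota)), sort(classes)))
    stop("severity_quota must be named with classes: ",
         paste(classes, collapse = ", "))
  severity_quota <- as.integer(severity_quota[classes])
  names(severity_quota) <- classes
  if (sum(severity_quota) != n_subjects)
    stop("severity_quota must sum to n_subjects (",
         sum(severity_quota), " != ", n_subjects, ")")
  if (!identical(sort(names(ahi_range)), sort(classes)))
    stop("ahi_range must be named with classes: ",
         paste(classes, collapse = ", "))
  ahi_range <- ahi_range[classes]
  if (ahi_range$none[2] > 5)
    stop("AHI interval of class 'none' must lie strictly below 5")
  lims <- do.call(rbind, ahi_range)
  if (any(lims[, 1] >= lims[, 2])) stop("ahi_range intervals must be non-empty")
  if (any(lims[-1, 1] < lims[-nrow(lims), 2]))
    stop("ahi_range intervals must be disjoint and increasing")
  if (rr_baseline <= 0) stop("rr_baseline must be positive")
  if (rr_modulation_depth < 0 || rr_modulation_depth >= 1)
    stop("rr_modulation_depth must be in [0, 1)")
  if (nan_rate < 0 || nan_rate >= 1) stop("nan_rate must be in [0, 1)")
  if (event_min <= 0) stop("event_min must be positive")
  if (fs <= 0) stop("fs must be positive")
  if (length(duration_range) != 2L || any(duration_range <= 0) ||
      duration_range[1] > duration_range[2])
    stop("duration_range must be an increasing positive pair of hours")
  structure(list(n_subjects = n_subjects,
                 severity_quota = severity_quota,
                 ahi_range = ahi_range,
                 duration_range = as.numeric(duration_range),
                 fs = fs,
                 event_meanlog = event_meanlog,
                 event_sdlog = event_sdlog,
                 event_min = event_min,
                 rr_baseline = rr_baseline,
                 rr_modulation_depth = rr_modulation_depth,
                 rr_jitter = rr_jitter,
                 noise_sd = noise_sd,
                 nan_rate = nan_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Positional-encoding configuration
#'
#' Selects and parameterizes one of the positional-encoding strategies added
#' to the transformer input: `"none"` (no positional information), `"naive"`
#' (normalized sequence index), `"sinusoidal"` (fixed sine/cosine table), or
#' `"autoencoder"` (a trainable content-aware encoding produced by a 1-D
#' convolutional autoencoder whose reconstruction-shaped output is added to
#' the input signal).
#'
#' @param strategy one of `"none"`, `"naive"`, `"sinusoidal"`, `"autoencoder"`.
#' @param sin_length row count of the reference sinusoidal table used by the
#'   `"tile"` length mode (default 64).
#' @param sin_mode `"full"` evaluates the sinusoidal table at the actual
#'   sequence length; `"tile"` builds a `sin_length`-row table and linearly
#'   resamples it to the sequence length.
#' @param ae_filters integer pair: filter counts of the two encoder
#'   convolutions (default `c(132, 64)`).
#' @param ae_dropout dropout rate applied inside the autoencoder.
#' @param ae_kernel convolution kernel width in samples (odd).
#' @param ae_training_mode `"joint"` trains the autoencoder end-to-end with
#'   the classification loss; `"pretrained"` first fits it on signal
#'   reconstruction (self-supervised: the targets are the inputs) and then
#'   freezes its weights.
#' @param ae_pretrain_epochs reconstruction epochs used by `"pretrained"` mode.
#' @return an object of class `posenc_config`.
#' @export
posenc_config <- function(strategy = c("autoencoder", "none", "naive",
                                       "sinusoidal"),
                          sin_length = 64L,
                          sin_mode = c("full", "tile"),
                          ae_filters = c(132L, 64L),
                          ae_dropout = 0.1,
                          ae_kernel = 7L,
                          ae_training_mode = c("joint", "pretrained"),
                          ae_pretrain_epochs = 3L) {
  strategy <- match.arg(strategy)
  sin_mode <- match.arg(sin_mode)
  ae_training_mode <- match.arg(ae_training_mode)
  if (ae_dropout < 0 || ae_dropout >= 1) stop("ae_dropout must be in [0, 1)")
  if (length(ae_filters) != 2L || any(ae_filters < 1))
    stop("ae_filters must be two positive filter counts")
  if (ae_kernel %% 2L != 1L) stop("ae_kernel must be odd")
  structure(list(strategy = strategy,
                 sin_length = as.integer(sin_length),
                 sin_mode = sin_mode,
                 ae_filters = as.integer(ae_filters),
                 ae_dropout = ae_dropout,
                 ae_kernel = as.integer(ae_kernel),
                 ae_training_mode = ae_training_mode,
                 ae_pretrain_epochs = as.integer(ae_pretrain_epochs)),
            class = "posenc_config")
}

#' Transformer classifier configuration
#'
#' Hyperparameters of the encoder-only transformer classifier. The defaults
#' are the best random-search configuration: 6 encoder blocks with 4
#' attention heads of per-head size 256, a 128-unit MLP head, dropout 0.1,
#' and a 30-unit sigmoid output (one probability per second of the window).
#'
#' `d_model` is the channel width of the residual stream. At the default
#' `d_model = 1` the raw univariate signal enters the encoder stack directly
#' (channel-preserving combination with the positional encoding). For
#' `d_model > 1` a learned pointwise input embedding lifts the signal to
#' `d_model` channels before the positional encoding is added; this is the
#' recommended setting for actual training, because channel-wise layer
#' normalization on a single channel is degenerate (see the package
#' vignette).
#'
#' @param num_blocks number of stacked encoder blocks.
#' @param num_heads attention heads per block.
#' @param head_size per-head key/query/value dimension.
#' @param ff_hidden hidden filter count of the pointwise feed-forward
#'   sublayer.
#' @param mlp_units hidden units of the classification head.
#' @param dropout dropout rate used throughout the model.
#' @param output_seconds number of per-second outputs per window.
#' @param d_model residual-stream channel width (1 = channel-preserving).
#' @param posenc a [posenc_config()].
#' @return an object of class `model_config`.
#' @export
model_config <- function(num_blocks = 6L,
                         num_heads = 4L,
                         head_size = 256L,
                         ff_hidden = 128L,
                         mlp_units = 128L,
                         dropout = 0.1,
                         output_seconds = 30L,
                         d_model = 1L,
                         posenc = posenc_config()) {
  counts <- c(num_blocks = num_blocks, num_heads = num_heads,
              head_size = head_size, ff_hidden = ff_hidden,
              mlp_units = mlp_units, output_seconds = output_seconds,
              d_model = d_model)
  if (any(counts < 1)) stop("all model size parameters must be positive")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (!inherits(posenc, "posenc_config")) stop("posenc must be a posenc_config")
  if (posenc$strategy == "sinusoidal" && (d_model < 2L || d_model %% 2L != 0L))
    stop("sinusoidal positional encoding requires an even d_model >= 2")
  structure(list(num_blocks = as.integer(num_blocks),
                 num_heads = as.integer(num_heads),
                 head_size = as.integer(head_size),
                 ff_hidden = as.integer(ff_hidden),
                 mlp_units = as.integer(mlp_units),
                 dropout = dropout,
                 output_seconds = as.integer(output_seconds),
                 d_model = as.integer(d_model),
                 posenc = posenc),
            class = "model_config")
}

#' Training configuration
#'
#' Optimization settings: AdamW (decoupled weight decay 1e-4) at batch size
#' 32 with initial learning rate 1e-3 held constant for 10 epochs, then
#' decayed exponentially (factor 0.9 per epoch) down to a floor of 1e-4.
#' Class weighting `"balanced"` reweights the per-second binary
#' cross-entropy so both classes carry equal total mass.
#'
#' @param batch_size windows per optimization step.
#' @param optimizer `"adamw"`, `"adam"`, or `"adam_amsgrad"`.
#' @param init_lr initial learning rate.
#' @param weight_decay decoupled weight decay coefficient (AdamW only).
#' @param lr_constant_epochs epochs at constant `init_lr` before decay.
#' @param lr_decay multiplicative decay factor per epoch after the constant
#'   phase.
#' @param lr_floor learning-rate floor.
#' @param epochs training epochs.
#' @param class_weighting `"balanced"` or `"none"`.
#' @param seed integer seed governing initialization, shuffling and dropout.
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 32L,
                         optimizer = c("adamw", "adam", "adam_amsgrad"),
                         init_lr = 1e-3,
                         weight_decay = 1e-4,
                         lr_constant_epochs = 10L,
                         lr_decay = 0.9,
                         lr_floor = 1e-4,
                         epochs = 20L,
                         class_weighting = c("balanced", "none"),
                         seed = 1L) {
  optimizer <- match.arg(optimizer)
  class_weighting <- match.arg(class_weighting)
  if (batch_size < 1L) stop("batch_size must be positive")
  if (init_lr <= 0) stop("init_lr must be positive")
  if (lr_floor > init_lr) stop("lr_floor must not exceed init_lr")
  if (lr_decay <= 0 || lr_decay > 1) stop("lr_decay must be in (0, 1]")
  if (epochs < 0L) stop("epochs must be non-negative")
  structure(list(batch_size = as.integer(batch_size),
                 optimizer = optimizer,
                 init_lr = init_lr,
                 weight_decay = weight_decay,
                 lr_constant_epochs = as.integer(lr_constant_epochs),
                 lr_decay = lr_decay,
                 lr_floor = lr_floor,
                 epochs = as.integer(epochs),
                 class_weighting = class_weighting,
                 seed = as.integer(seed)),
            class = "train_config")
}
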