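# Class-weighted training with AdamW and a constant-then-decay schedule,
# plus patient-level splitting utilities. All randomness (initialization,
# shuffling, dropout) is governed by the training seed.

#' Balanced class weights for per-second labels
#'
#' The balanced scheme `w_c = N / (2 * N_c)`: the weighted mass of the two
#' classes is exactly equal, which counteracts the roughly 1:6
#' apnea:normal imbalance of overnight recordings.
#'
#' @param labels binary vector or matrix of per-second labels.
#' @return named list with `weight_pos`, `weight_neg`.
#' @export
class_weights <- function(labels) {
  y <- as.vector(labels)
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute class weights")
  n <- n_pos + n_neg
  list(weight_pos = n / (2 * n_pos), weight_neg = n / (2 * n_neg))
}

#' Learning rate at a given epoch
#'
#' Constant at `init_lr` through `lr_constant_epochs`, then multiplied by
#' `lr_decay` each epoch, floored at `lr_floor`.
#'
#' @param epoch 1-based epoch number.
#' @param config a [train_config()].
#' @return the learning rate.
#' @export
lr_schedule <- function(epoch, config = train_config()) {
  if (epoch <= config$lr_constant_epochs) return(config$init_lr)
  max(config$init_lr * config$lr_decay^(epoch - config$lr_constant_epochs),
      config$lr_floor)
}

#' Weighted binary cross-entropy from logits
#'
#' Numerically stable per-element binary cross-entropy, each element
#' weighted by its class weight, averaged over all elements. With weights
#' `(1, 1)` this is exactly the unweighted loss.
#'
#' @param logits matrix of logits.
#' @param y matching binary label matrix.
#' @param weights list with `weight_pos`, `weight_neg`.
#' @return list with `loss` (scalar) and `dlogits` (gradient matrix).
#' @export
weighted_bce <- function(logits, y,
                         weights = list(weight_pos = 1, weight_neg = 1)) {
  w <- ifelse(y == 1, weights$weight_pos, weights$weight_neg)
  # softplus(z) - z*y, stable for large |z|
  bce <- pmax(logits, 0) - logits * y + log1p(exp(-abs(logits)))
  n <- length(logits)
  list(loss = sum(w * bce) / n,
       dlogits = w * (sigmoid(logits) - y) / n)
}

## ---- Adam-family optimizers ----

adam_init <- function(params) {
  flat <- flatten_tree(params)
  zeros <- lapply(flat, function(x) array(0, dim(x) %||% length(x)))
  list(m = zeros, v = zeros, vhat = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, tconfig) {
  flat_p <- flatten_tree(params)
  flat_g <- flatten_tree(grads)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-7
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  amsgrad <- tconfig$optimizer == "adam_amsgrad"
  decoupled <- tconfig$optimizer == "adamw"
  for (nm in names(flat_p)) {
    g <- flat_g[[nm]]
    if (is.null(g)) next  # frozen component
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    v_use <- if (amsgrad) {
      state$vhat[[nm]] <- pmax(state$vhat[[nm]], state$v[[nm]])
      state$vhat[[nm]]
    } else state$v[[nm]]
    upd <- (state$m[[nm]] / c1) / (sqrt(v_use / c2) + eps)
    # decoupled weight decay on weight matrices only (leaf names `W*`)
    leaf <- sub(".*\\.", "", nm)
    if (decoupled && startsWith(leaf, "W"))
      upd <- upd + tconfig$weight_decay * flat_p[[nm]]
    flat_p[[nm]] <- flat_p[[nm]] - lr * upd
  }
  list(params = unflatten_into(params, flat_p), state = state)
}

## ---- patient-level splitting ----

#' Split subjects into development and test sets
#'
#' A seeded random subject-level partition; every window of a subject
#' follows its subject, so no subject's data can leak across the split.
#'
#' @param subject_ids character vector of unique subject identifiers.
#' @param test_fraction fraction of subjects held out.
#' @param seed integer seed.
#' @return a `split_plan`: list with `dev` and `test` subject-id vectors.
#' @export
split_patients <- function(subject_ids, test_fraction = 0.2, seed = 1L) {
  subject_ids <- unique(subject_ids)
  if (length(subject_ids) < 5L) stop("need at least 5 subjects to split")
  n_test <- max(1L, round(test_fraction * length(subject_ids)))
  test <- withr::with_seed(seed, sample(subject_ids, n_test))
  structure(list(dev = setdiff(subject_ids, test), test = test),
            class = "split_plan")
}

#' Patient-level cross-validation folds
#'
#' `"nested"` (default) partitions the development subjects into `k`
#' near-equal validation folds: every subject validates exactly once and no
#' subject is in both train and validation of any fold. `"literal_23_7"`
#' reproduces the historically reported 23-train / 7-validation arithmetic
#' over a 30-subject cohort: `k` independent seeded 23/7 splits of all
#' subjects (not a partition; a subject may validate in more than one
#' fold).
#'
#' @param dev_subjects subject ids to fold.
#' @param k number of folds.
#' @param seed integer seed.
#' @param mode `"nested"` or `"literal_23_7"`.
#' @return list of `k` folds, each a list with `train` and `val`.
#' @export
make_folds <- function(dev_subjects, k = 5L, seed = 1L,
                       mode = c("nested", "literal_23_7")) {
  mode <- match.arg(mode)
  if (k <= 1L) stop("k must be at least 2")
  if (mode == "nested") {
    if (k > length(dev_subjects)) stop("k exceeds the number of subjects")
    shuffled <- withr::with_seed(seed, sample(dev_subjects))
    assignment <- sort(rep_len(seq_len(k), length(shuffled)))
    lapply(seq_len(k), function(f) {
      val <- shuffled[assignment == f]
      list(train = setdiff(dev_subjects, val), val = val)
    })
  } else {
    n_val <- 7L
    if (length(dev_subjects) <= n_val)
      stop("literal_23_7 mode needs more than 7 subjects")
    withr::with_seed(seed, lapply(seq_len(k), function(f) {
      val <- sample(dev_subjects, n_val)
      list(train = setdiff(dev_subjects, val), val = val)
    }))
  }
}

## ---- training loop ----

# Self-supervised reconstruction fit of the autoencoder PE (pretrained
# mode): the targets are the inputs themselves, mean-squared error.
pretrain_autoencoder <- function(model, X, tconfig) {
  pconf <- model$config$posenc
  ae <- model$params$ae
  state <- adam_init(ae)
  n <- nrow(X)
  for (epoch in seq_len(pconf$ae_pretrain_epochs)) {
    ord <- sample(n)
    for (batch in split(ord, ceiling(seq_along(ord) / tconfig$batch_size))) {
      A <- array(t(X[batch, , drop = FALSE]), c(ncol(X), length(batch), 1L))
      fw <- ae_fwd(A, ae, pconf, training = TRUE)
      target <- array(A, dim(fw$out))  # signal replicated per output channel
      dY <- 2 * (fw$out - target) / length(fw$out)
      bw <- ae_bwd(dY, fw$cache, dim(A)[1], dim(A)[2])
      upd <- adam_step(ae, bw$grads, state, tconfig$init_lr, tconfig)
      ae <- upd$params
      state <- upd$state
    }
  }
  ae
}

#' Train the apnea classifier
#'
#' Mini-batch training of the per-second weighted binary cross-entropy with
#' the configured optimizer and learning-rate schedule. Fully seeded: the
#' same `(model, dataset, config)` yields the same trained weights. With
#' `epochs = 0` the initialized model is returned unchanged.
#'
#' @param model an `apnea_classifier` from [build_classifier()].
#' @param dataset an `apnea_dataset` (or list with `X`, `y`).
#' @param tconfig a [train_config()].
#' @return list with `model` (trained) and `history` (data frame with
#'   `epoch`, `loss`, `lr`).
#' @export
train_classifier <- function(model, dataset, tconfig = train_config()) {
  X <- dataset$X
  if (length(dim(X)) == 3L) X <- X[, , 1L, drop = TRUE]
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  y <- dataset$y
  n <- nrow(X)
  if (n == 0L) stop("training dataset is empty")
  if (length(unique(as.vector(y))) < 2L)
    stop("training labels contain a single class; generate a cohort with ",
         "both apnea and normal seconds or disable class weighting")
  weights <- if (tconfig$class_weighting == "balanced") {
    cw <- class_weights(y)
    list(weight_pos = cw$weight_pos, weight_neg = cw$weight_neg)
  } else list(weight_pos = 1, weight_neg = 1)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        lr = numeric(0))
  if (tconfig$epochs == 0L) return(list(model = model, history = history))
  withr::with_seed(tconfig$seed, {
    ae_frozen <- FALSE
    if (model$config$posenc$strategy == "autoencoder" &&
        model$config$posenc$ae_training_mode == "pretrained") {
      model$params$ae <- pretrain_autoencoder(model, X, tconfig)
      ae_frozen <- TRUE
    }
    state <- adam_init(model$params)
    for (epoch in seq_len(tconfig$epochs)) {
      lr <- lr_schedule(epoch, tconfig)
      ord <- sample(n)
      batch_losses <- numeric(0)
      for (batch in split(ord, ceiling(seq_along(ord) / tconfig$batch_size))) {
        fw <- model_forward(model, X[batch, , drop = FALSE], training = TRUE)
        lo <- weighted_bce(fw$logits, y[batch, , drop = FALSE], weights)
        gr <- model_backward(model, fw$cache, lo$dlogits)
        if (ae_frozen) gr$ae <- NULL
        upd <- adam_step(model$params, gr, state, lr, tconfig)
        model$params <- upd$params
        state <- upd$state
        batch_losses <- c(batch_losses, lo$loss)
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = mean(batch_losses),
                                  lr = lr))
    }
  })
  list(model = model, history = history)
}
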