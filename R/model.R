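# Encoder-only transformer classifier.
#
# Pipeline: (optional pointwise input embedding to d_model channels) ->
# positional-encoding combination -> stacked encoder blocks -> global
# average pooling over time -> dense ReLU head -> 30-unit sigmoid output,
# one probability per second of the window. Each encoder block is
# post-norm: multi-head self-attention -> dropout -> residual -> layer
# norm, then pointwise convolution (ReLU) -> dropout -> pointwise
# convolution -> residual -> layer norm.

#' Build one transformer encoder block's parameters
#'
#' @param config a [model_config()].
#' @param d_model channel width of the residual stream.
#' @return parameter list (attention projections, feed-forward weights,
#'   layer-norm gains/biases). Weights use uniform fan-based
#'   initialization drawn from the current RNG state.
#' @export
build_encoder_block <- function(config, d_model = config$d_model) {
  hd <- config$num_heads * config$head_size
  list(Wq = init_mat(d_model, hd), bq = numeric(hd),
       Wk = init_mat(d_model, hd), bk = numeric(hd),
       Wv = init_mat(d_model, hd), bv = numeric(hd),
       Wo = init_mat(hd, d_model), bo = numeric(d_model),
       ln1_g = rep(1, d_model), ln1_b = numeric(d_model),
       W1 = init_mat(d_model, config$ff_hidden), b1 = numeric(config$ff_hidden),
       W2 = init_mat(config$ff_hidden, d_model), b2 = numeric(d_model),
       ln2_g = rep(1, d_model), ln2_b = numeric(d_model))
}

encoder_block_fwd <- function(A, p, config, training = FALSE, keep = TRUE) {
  L <- dim(A)[1]; n <- dim(A)[2]
  at <- mha_fwd(A, p, config$num_heads, config$head_size, keep = keep)
  ad <- dropout_fwd(at$out, config$dropout, training)
  l1 <- layernorm_fwd(A + ad$out, p$ln1_g, p$ln1_b)
  f1 <- dense_fwd(l1$out, p$W1, p$b1)
  r1 <- relu(f1$out)
  fd <- dropout_fwd(r1, config$dropout, training)
  f2 <- dense_fwd(fd$out, p$W2, p$b2)
  l2 <- layernorm_fwd(l1$out + f2$out, p$ln2_g, p$ln2_b)
  list(out = l2$out,
       cache = list(at = at, ad = ad, l1 = l1, f1 = f1, r1 = r1,
                    fd = fd, f2 = f2, l2 = l2))
}

encoder_block_bwd <- function(dY, cache, L, n) {
  b2 <- layernorm_bwd(dY, cache$l2$cache, L, n)
  bf2 <- dense_bwd(b2$dA, cache$f2$cache, L, n)
  dr1 <- dropout_bwd(bf2$dA, cache$fd$mask) * (cache$r1 > 0)
  bf1 <- dense_bwd(dr1, cache$f1$cache, L, n)
  dl1out <- b2$dA + bf1$dA
  b1 <- layernorm_bwd(dl1out, cache$l1$cache, L, n)
  bad <- dropout_bwd(b1$dA, cache$ad$mask)
  bat <- mha_bwd(bad, cache$at$cache, L, n)
  grads <- c(bat$grads,
             list(ln1_g = b1$dg, ln1_b = b1$db,
                  W1 = bf1$dW, b1 = bf1$db,
                  W2 = bf2$dW, b2 = bf2$db,
                  ln2_g = b2$dg, ln2_b = b2$db))
  list(dA = b1$dA + bat$dA, grads = grads)
}

#' Build the apnea classifier
#'
#' Initializes all trainable parameters (seeded) and precomputes any static
#' positional-encoding table at the model's sequence length.
#'
#' @param config a [model_config()].
#' @param seq_len input sequence length in samples (window seconds times
#'   sampling frequency).
#' @param seed integer seed for weight initialization.
#' @return an `apnea_classifier`.
#' @export
build_classifier <- function(config, seq_len, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  seq_len <- as.integer(seq_len)
  if (seq_len < 1L) stop("seq_len must be positive")
  params <- withr::with_seed(seed, {
    p <- list()
    if (config$d_model > 1L)
      p$embed <- list(W = init_mat(1L, config$d_model),
                      b = numeric(config$d_model))
    if (config$posenc$strategy == "autoencoder")
      p$ae <- build_autoencoder_pe(config$posenc,
                                   seed = sample.int(.Machine$integer.max, 1),
                                   out_channels = config$d_model)
    p$blocks <- stats::setNames(
      lapply(seq_len(config$num_blocks), function(i) build_encoder_block(config)),
      paste0("block", seq_len(config$num_blocks)))
    p$head <- list(Wm = init_mat(config$d_model, config$mlp_units),
                   bm = numeric(config$mlp_units),
                   Wc = init_mat(config$mlp_units, config$output_seconds),
                   bc = numeric(config$output_seconds))
    p
  })
  structure(list(params = params,
                 config = config,
                 seq_len = seq_len,
                 static_pe = static_encoding(config$posenc, seq_len,
                                             config$d_model),
                 init_seed = as.integer(seed)),
            class = "apnea_classifier")
}

# Coerce user input (n x L matrix or n x L x 1 array) to internal (L, n, 1).
input_to_internal <- function(X, seq_len) {
  if (length(dim(X)) == 3L) X <- X[, , 1L, drop = TRUE]
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != seq_len)
    stop("sequence length ", ncol(X), " does not match the model's ", seq_len)
  array(t(X), c(seq_len, nrow(X), 1L))
}

model_forward <- function(model, X, training = FALSE, keep_cache = TRUE) {
  cfg <- model$config
  L <- model$seq_len
  A0 <- input_to_internal(X, L)
  n <- dim(A0)[2]
  C <- cfg$d_model
  cache <- list(n = n)
  if (C > 1L) {
    em <- dense_fwd(A0, model$params$embed$W, model$params$embed$b)
    A <- em$out
    cache$embed <- em$cache
  } else A <- A0
  strat <- cfg$posenc$strategy
  if (strat %in% c("naive", "sinusoidal") && !is.null(model$static_pe)) {
    pe <- model$static_pe
    if (is.matrix(pe)) {
      for (c in seq_len(C)) A[, , c] <- A[, , c] + pe[, c]
    } else {
      A <- A + pe  # length-L vector recycles down the sequence axis
    }
  } else if (strat == "autoencoder") {
    ae <- ae_fwd(A0, model$params$ae, cfg$posenc, training)
    A <- A + ae$out  # channelwise: the convt restores d_model channels
    cache$ae <- ae$cache
  }
  cache$blocks <- vector("list", cfg$num_blocks)
  for (b in seq_len(cfg$num_blocks)) {
    bl <- encoder_block_fwd(A, model$params$blocks[[b]], cfg, training,
                            keep = keep_cache)
    A <- bl$out
    cache$blocks[[b]] <- bl$cache
  }
  P <- colMeans(A, dims = 1)           # (n, C) pooled over time
  if (is.null(dim(P))) P <- matrix(P, ncol = 1L)
  h1 <- add_bias(P %*% model$params$head$Wm, model$params$head$bm)
  hr <- relu(h1)
  hd <- dropout_fwd(hr, cfg$dropout, training)
  logits <- add_bias(hd$out %*% model$params$head$Wc, model$params$head$bc)
  cache$P <- P; cache$hr <- hr; cache$hd <- hd
  list(probs = sigmoid(logits), logits = logits, cache = cache)
}

model_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  L <- model$seq_len
  n <- cache$n
  C <- cfg$d_model
  p <- model$params
  grads <- list()
  dhd <- dlogits %*% t(p$head$Wc)
  dWc <- crossprod(cache$hd$out, dlogits)
  dbc <- colSums(dlogits)
  dh1 <- dropout_bwd(dhd, cache$hd$mask) * (cache$hr > 0)
  dWm <- crossprod(cache$P, dh1)
  dbm <- colSums(dh1)
  dP <- dh1 %*% t(p$head$Wm)
  grads$head <- list(Wm = dWm, bm = dbm, Wc = dWc, bc = dbc)
  dA <- array(0, c(L, n, C))
  for (c in seq_len(C)) dA[, , c] <- matrix(dP[, c] / L, L, n, byrow = TRUE)
  grads$blocks <- vector("list", cfg$num_blocks)
  names(grads$blocks) <- names(p$blocks)
  for (b in rev(seq_len(cfg$num_blocks))) {
    bb <- encoder_block_bwd(dA, cache$blocks[[b]], L, n)
    dA <- bb$dA
    grads$blocks[[b]] <- bb$grads
  }
  if (cfg$posenc$strategy == "autoencoder") {
    aeb <- ae_bwd(dA, cache$ae, L, n)
    grads$ae <- aeb$grads
  }
  if (C > 1L) {
    emb <- dense_bwd(dA, cache$embed, L, n)
    grads$embed <- list(W = emb$dW, b = emb$db)
  }
  grads[names(p)]  # order like params
}

#' Per-second apnea predictions
#'
#' Evaluation-mode forward pass (dropout disabled) in batches, thresholded
#' to binary calls. Probabilities are returned for ROC analysis.
#'
#' @param model an `apnea_classifier`.
#' @param X input windows: `n x L` matrix, `n x L x 1` array, or an
#'   `apnea_dataset` (its `X` is used).
#' @param threshold probability threshold for a positive call.
#' @param batch_size windows per forward pass.
#' @return list with `prob` and `pred` (`n x output_seconds` matrices).
#' @export
predict_seconds <- function(model, X, threshold = 0.5, batch_size = 64L) {
  if (inherits(X, "apnea_dataset")) X <- X$X
  if (length(dim(X)) == 3L) X <- X[, , 1L, drop = TRUE]
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  n <- nrow(X)
  S <- model$config$output_seconds
  prob <- matrix(0, n, S)
  for (chunk in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    prob[chunk, ] <- model_forward(model, X[chunk, , drop = FALSE],
                                   training = FALSE, keep_cache = FALSE)$probs
  }
  list(prob = prob, pred = (prob >= threshold) * 1L)
}

#' Number of trainable parameters
#'
#' @param model an `apnea_classifier`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(flatten_tree(model$params), length, integer(1)))
}

#' @export
print.apnea_classifier <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<apnea_classifier> seq_len %d, d_model %d, %d blocks ",
                     "(%d heads x %d), posenc '%s', %s parameters\n"),
              x$seq_len, cfg$d_model, cfg$num_blocks, cfg$num_heads,
              cfg$head_size, cfg$posenc$strategy,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Save a classifier checkpoint
#'
#' Writes the model in R's native serialized format plus a JSON sidecar
#' holding the full model configuration for reproducibility.
#'
#' @param model an `apnea_classifier`.
#' @param path output `.rds` path; the sidecar uses the same base name with
#'   `.json`.
#' @return invisibly, `path`.
#' @export
save_classifier <- function(model, path) {
  saveRDS(model, path)
  sidecar <- sub("\\.rds$", ".json", path)
  cfg <- model$config
  cfg$posenc <- unclass(cfg$posenc)
  jsonlite::write_json(list(config = unclass(cfg), seq_len = model$seq_len,
                            init_seed = model$init_seed,
                            n_parameters = n_parameters(model)),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a classifier checkpoint
#'
#' @param path `.rds` path written by [save_classifier()].
#' @return the `apnea_classifier`.
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "apnea_classifier"))
  model
}
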