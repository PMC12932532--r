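# Positional-encoding strategies.
#
# Three ways of telling the encoder where each sample sits in the window:
# a normalized index (naive), the classic fixed sine/cosine table
# (sinusoidal), and a trainable content-aware encoding produced by a 1-D
# convolutional autoencoder whose reconstruction-shaped output is added to
# the input signal. The static variants are pure functions of (length,
# depth) and never depend on the input; the autoencoder variant depends on
# the input by design.

#' Naive positional encoding
#'
#' The normalized sequence index: value `i / (length - 1)` at 0-based
#' position `i`, so the encoding runs strictly increasing from 0 to 1.
#'
#' @param length sequence length (positions).
#' @return numeric vector of `length` values in `[0, 1]`; `length = 1`
#'   gives `0`.
#' @export
naive_encoding <- function(length) {
  if (length < 1) stop("length must be >= 1")
  if (length == 1L) return(0)
  (seq_len(length) - 1) / (length - 1)
}

#' Sinusoidal positional encoding
#'
#' The fixed sine/cosine table: `PE[pos, 2i] = sin(pos / 10000^(2i/d))` and
#' `PE[pos, 2i + 1] = cos(pos / 10000^(2i/d))` with 0-based `pos` and `i`.
#'
#' @param length number of positions (rows).
#' @param d_model even embedding depth (columns).
#' @return matrix `length x d_model` with entries in `[-1, 1]`.
#' @export
sinusoidal_encoding <- function(length, d_model) {
  if (length < 1) stop("length must be >= 1")
  if (d_model %% 2 != 0) stop("d_model must be even")
  pos <- seq_len(length) - 1
  i <- seq_len(d_model / 2) - 1
  ang <- outer(pos, 1 / 10000^(2 * i / d_model))
  pe <- matrix(0, length, d_model)
  pe[, 2 * i + 1] <- sin(ang)
  pe[, 2 * i + 2] <- cos(ang)
  pe
}

# Linearly resample a pe table (rows = positions) to a new length.
resample_rows <- function(pe, new_length) {
  old <- nrow(pe)
  if (old == new_length) return(pe)
  at <- seq(1, old, length.out = new_length)
  apply(pe, 2, function(col) stats::approx(seq_len(old), col, xout = at)$y)
}

# Build the static encoding used by a model at a given sequence length, or
# NULL for strategies without a static table.
static_encoding <- function(pconf, seq_len, d_model) {
  switch(pconf$strategy,
         none = NULL,
         naive = naive_encoding(seq_len),
         sinusoidal = {
           if (pconf$sin_mode == "full") sinusoidal_encoding(seq_len, d_model)
           else resample_rows(sinusoidal_encoding(pconf$sin_length, d_model),
                              seq_len)
         },
         autoencoder = NULL)
}

#' Initialize the autoencoder positional-encoding component
#'
#' Architecture: 1-D convolution (`ae_filters[1]` filters, ReLU) ->
#' dropout -> 1-D convolution (`ae_filters[2]` filters, ReLU) -> transposed
#' convolution restoring the input's length and single channel. At stride 1
#' with symmetric zero padding the transposed convolution is the
#' correlation with a flipped kernel, so it is realized as a trainable
#' convolution with its own weights. Output shape equals input shape for
#' any length, which is what lets the reconstruction-shaped embedding be
#' added elementwise to the signal.
#'
#' @param config a [posenc_config()] with `strategy = "autoencoder"`.
#' @param seed integer seed for weight initialization.
#' @param out_channels channel count restored by the transposed
#'   convolution: 1 for the raw signal, or the model's embedding width so
#'   the encoding is added channelwise to the embedded stream (a
#'   per-channel encoding survives channel-wise layer normalization,
#'   which subtracts any component shared by all channels).
#' @return parameter list (`conv1`, `conv2`, `convt`, each `W`/`b`).
#' @export
build_autoencoder_pe <- function(config = posenc_config("autoencoder"),
                                 seed = 1L, out_channels = 1L) {
  k <- config$ae_kernel
  f <- config$ae_filters
  withr::with_seed(seed, list(
    conv1 = list(W = init_mat(k * 1L, f[1]), b = numeric(f[1])),
    conv2 = list(W = init_mat(k * f[1], f[2]), b = numeric(f[2])),
    convt = list(W = init_mat(k * f[2], out_channels),
                 b = numeric(out_channels))
  ))
}

# Forward pass of the autoencoder PE on an (L, n, 1) array.
ae_fwd <- function(A, p, pconf, training = FALSE) {
  k <- pconf$ae_kernel
  c1 <- conv1d_fwd(A, p$conv1$W, p$conv1$b, k)
  r1 <- relu(c1$out)
  dp <- dropout_fwd(r1, pconf$ae_dropout, training)
  c2 <- conv1d_fwd(dp$out, p$conv2$W, p$conv2$b, k)
  r2 <- relu(c2$out)
  ct <- conv1d_fwd(r2, p$convt$W, p$convt$b, k)
  list(out = ct$out,
       cache = list(c1 = c1, r1 = r1, dp = dp, c2 = c2, r2 = r2, ct = ct))
}

ae_bwd <- function(dY, cache, L, n) {
  bt <- conv1d_bwd(dY, cache$ct$cache, L, n)
  d2 <- bt$dA * (cache$r2 > 0)
  b2 <- conv1d_bwd(d2, cache$c2$cache, L, n)
  d1 <- dropout_bwd(b2$dA, cache$dp$mask) * (cache$r1 > 0)
  b1 <- conv1d_bwd(d1, cache$c1$cache, L, n)
  list(dA = b1$dA,
       grads = list(conv1 = list(W = b1$dW, b = b1$db),
                    conv2 = list(W = b2$dW, b = b2$db),
                    convt = list(W = bt$dW, b = bt$db)))
}

#' Run the autoencoder positional-encoding component
#'
#' Evaluation-mode forward pass (dropout disabled): signal in, embedding of
#' identical shape out.
#'
#' @param params parameters from [build_autoencoder_pe()].
#' @param x numeric vector (one window) or matrix `n x L` (one row per
#'   window).
#' @param config the matching [posenc_config()].
#' @return embedding with the same shape as `x`.
#' @export
autoencoder_pe <- function(params, x, config = posenc_config("autoencoder")) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, 1L) else x
  A <- array(t(X), c(ncol(X), nrow(X), 1L))
  out <- ae_fwd(A, params, config, training = FALSE)$out
  R <- t(matrix(out, dim(A)[1], dim(A)[2]))
  if (vec) as.vector(R) else R
}

#' Combine an input sequence with a static positional encoding
#'
#' The combination is additive: `Z = inputE(x) + PE`. For `"none"` the
#' input embedding is the identity and `Z = x`; for `"naive"` the
#' length-`L` encoding vector is broadcast over channels; for
#' `"sinusoidal"` the input must already carry `d_model` channels (the
#' model applies its learned pointwise embedding first) and the `L x
#' d_model` table is added elementwise.
#'
#' @param x numeric vector (one channel) or `L x C` matrix.
#' @param encoding `NULL`, a length-`L` vector, or an `L x C` matrix.
#' @param strategy `"none"`, `"naive"`, or `"sinusoidal"`.
#' @return the combined sequence, same shape as `x`.
#' @export
combine_posenc <- function(x, encoding,
                           strategy = c("none", "naive", "sinusoidal")) {
  strategy <- match.arg(strategy)
  if (strategy == "none") return(x)
  L <- if (is.null(dim(x))) length(x) else nrow(x)
  if (strategy == "naive") {
    if (length(encoding) != L) stop("encoding length must match the sequence")
    return(x + encoding)
  }
  if (!is.matrix(x) || !is.matrix(encoding) || !all(dim(x) == dim(encoding)))
    stop("sinusoidal combination requires matching L x d_model shapes")
  x + encoding
}
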