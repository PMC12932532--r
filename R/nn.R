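# Neural-network primitives on plain R matrix algebra.
#
# Activations flow through the model as 3-D arrays with dims (L, n, C):
# sequence position, window (batch), channel. Column-major layout makes the
# (L*n) x C matrix view `nn_mat()` free of copying semantics headaches: each
# window occupies a contiguous block of L rows, which is what the attention
# loops index. Every layer comes as a `_fwd` returning (out, cache) and a
# `_bwd` consuming the upstream gradient, so the whole classifier is
# differentiated by hand; correctness is pinned by finite-difference tests.

nn_mat <- function(A) {
  d <- dim(A)
  dim(A) <- c(d[1] * d[2], d[3])
  A
}

nn_arr <- function(M, L, n) {
  array(M, c(L, n, ncol(M)))
}

# add a row vector to every row
add_bias <- function(M, b) M + rep(b, each = nrow(M))

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) stats::plogis(x)

# Glorot/fan-based uniform initialization
init_mat <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
}

## ---- pointwise dense (kernel-size-1 convolution) ----

dense_fwd <- function(A, W, b) {
  M <- nn_mat(A)
  Y <- add_bias(M %*% W, b)
  list(out = nn_arr(Y, dim(A)[1], dim(A)[2]), cache = list(M = M, W = W))
}

dense_bwd <- function(dY, cache, L, n) {
  dM <- nn_mat(dY)
  list(dA = nn_arr(dM %*% t(cache$W), L, n),
       dW = crossprod(cache$M, dM),
       db = colSums(dM))
}

## ---- 1-D convolution, stride 1, zero ("same") padding ----

# shift along the sequence axis: out[l, , ] = A[l + o, , ], zero-filled
shift_seq <- function(A, o) {
  if (o == 0L) return(A)
  L <- dim(A)[1]
  S <- array(0, dim(A))
  if (o > 0) {
    if (o < L) S[1:(L - o), , ] <- A[(1 + o):L, , , drop = FALSE]
  } else {
    if (-o < L) S[(1 - o):L, , ] <- A[1:(L + o), , , drop = FALSE]
  }
  S
}

# W has dim (k * Cin, Cout): tap-major rows (tap 1 channels, tap 2 channels, ...)
conv1d_fwd <- function(A, W, b, k) {
  L <- dim(A)[1]; n <- dim(A)[2]; Cin <- dim(A)[3]
  p <- (k - 1L) %/% 2L
  Xc <- matrix(0, L * n, k * Cin)
  for (j in seq_len(k)) {
    Xc[, ((j - 1L) * Cin + 1L):(j * Cin)] <- nn_mat(shift_seq(A, j - p - 1L))
  }
  Y <- add_bias(Xc %*% W, b)
  list(out = nn_arr(Y, L, n), cache = list(Xc = Xc, W = W, k = k, Cin = Cin))
}

conv1d_bwd <- function(dY, cache, L, n) {
  k <- cache$k; Cin <- cache$Cin
  p <- (k - 1L) %/% 2L
  dM <- nn_mat(dY)
  dXc <- dM %*% t(cache$W)
  dA <- array(0, c(L, n, Cin))
  for (j in seq_len(k)) {
    dS <- nn_arr(dXc[, ((j - 1L) * Cin + 1L):(j * Cin), drop = FALSE], L, n)
    dA <- dA + shift_seq(dS, -(j - p - 1L))
  }
  list(dA = dA, dW = crossprod(cache$Xc, dM), db = colSums(dM))
}

## ---- layer normalization over the channel axis ----

layernorm_fwd <- function(A, g, b, eps = 1e-6) {
  M <- nn_mat(A)
  mu <- rowMeans(M)
  xc <- M - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- add_bias(xhat * rep(g, each = nrow(M)), b)
  list(out = nn_arr(Y, dim(A)[1], dim(A)[2]),
       cache = list(xhat = xhat, inv = inv, g = g))
}

layernorm_bwd <- function(dY, cache, L, n) {
  dM <- nn_mat(dY)
  dxhat <- dM * rep(cache$g, each = nrow(dM))
  xhat <- cache$xhat
  dX <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dA = nn_arr(dX, L, n),
       dg = colSums(dM * xhat),
       db = colSums(dM))
}

## ---- dropout (inverted scaling; identity when not training) ----

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  mask <- array((stats::runif(length(x)) >= rate) / (1 - rate), dim(x) %||% length(x))
  list(out = x * mask, mask = mask)
}

dropout_bwd <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- softmax over rows ----

softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

## ---- multi-head self-attention ----

# params: Wq, bq, Wk, bk, Wv, bv  (C x H*dk),  Wo, bo  (H*dk x C)
mha_fwd <- function(A, p, H, dk, keep = TRUE) {
  L <- dim(A)[1]; n <- dim(A)[2]
  M <- nn_mat(A)
  Qm <- add_bias(M %*% p$Wq, p$bq)
  Km <- add_bias(M %*% p$Wk, p$bk)
  Vm <- add_bias(M %*% p$Wv, p$bv)
  Hm <- matrix(0, L * n, H * dk)
  att <- vector("list", n)
  scale <- 1 / sqrt(dk)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * L + 1L):(i * L)
    att[[i]] <- vector("list", H)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      S <- tcrossprod(Qm[rows, cols, drop = FALSE],
                      Km[rows, cols, drop = FALSE]) * scale
      Amat <- softmax_rows(S)
      att[[i]][[h]] <- Amat
      Hm[rows, cols] <- Amat %*% Vm[rows, cols, drop = FALSE]
    }
  }
  O <- add_bias(Hm %*% p$Wo, p$bo)
  # the attention matrices dominate memory (n*H matrices of L^2); only keep
  # them when a backward pass will follow
  cache <- if (keep)
    list(M = M, Qm = Qm, Km = Km, Vm = Vm, Hm = Hm, att = att,
         p = p, H = H, dk = dk)
  list(out = nn_arr(O, L, n), cache = cache)
}

mha_bwd <- function(dY, cache, L, n) {
  p <- cache$p; H <- cache$H; dk <- cache$dk
  scale <- 1 / sqrt(dk)
  dO <- nn_mat(dY)
  dWo <- crossprod(cache$Hm, dO)
  dbo <- colSums(dO)
  dHm <- dO %*% t(p$Wo)
  dQm <- matrix(0, L * n, H * dk)
  dKm <- dQm
  dVm <- dQm
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * L + 1L):(i * L)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      Amat <- cache$att[[i]][[h]]
      V <- cache$Vm[rows, cols, drop = FALSE]
      dHh <- dHm[rows, cols, drop = FALSE]
      dA <- tcrossprod(dHh, V)
      dVm[rows, cols] <- crossprod(Amat, dHh)
      dS <- Amat * (dA - rowSums(dA * Amat))
      dQm[rows, cols] <- dS %*% cache$Km[rows, cols, drop = FALSE] * scale
      dKm[rows, cols] <- crossprod(dS, cache$Qm[rows, cols, drop = FALSE]) * scale
    }
  }
  dM <- dQm %*% t(p$Wq) + dKm %*% t(p$Wk) + dVm %*% t(p$Wv)
  list(dA = nn_arr(dM, L, n),
       grads = list(Wq = crossprod(cache$M, dQm), bq = colSums(dQm),
                    Wk = crossprod(cache$M, dKm), bk = colSums(dKm),
                    Wv = crossprod(cache$M, dVm), bv = colSums(dVm),
                    Wo = dWo, bo = dbo))
}

## ---- parameter-tree utilities ----

tree_map <- function(x, f) {
  if (is.list(x)) lapply(x, tree_map, f = f) else f(x)
}

flatten_tree <- function(x, prefix = "") {
  if (!is.list(x)) return(stats::setNames(list(x), prefix))
  out <- list()
  for (nm in names(x)) {
    child <- paste0(prefix, if (nzchar(prefix)) "." else "", nm)
    out <- c(out, flatten_tree(x[[nm]], child))
  }
  out
}

unflatten_into <- function(template, flat) {
  rec <- function(x, prefix) {
    if (!is.list(x)) return(flat[[prefix]])
    for (nm in names(x)) {
      child <- paste0(prefix, if (nzchar(prefix)) "." else "", nm)
      x[[nm]] <- rec(x[[nm]], child)
    }
    x
  }
  rec(template, "")
}
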