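# Neural-network primitives with explicit forward/backward passes.
#
# Activations are matrices of shape (B*T, C): B samples, T time steps, C
# channels, rows ordered sample-major so that row index of (b, t) is
# b + (t-1)*B. This makes every linear layer a single BLAS matmul over the
# whole batch; only attention and time-shifts need per-sample indexing.

rows_of <- function(b, B, T) b + (seq_len(T) - 1L) * B

bcast_row <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

# output row (b,t) = input row (b, t+o), zero-padded outside the sequence
shift_time <- function(M, B, T, o) {
  if (o == 0L) return(M)
  out <- matrix(0, nrow(M), ncol(M))
  tdst <- which(seq_len(T) + o >= 1L & seq_len(T) + o <= T)
  if (length(tdst)) {
    dst <- as.vector(outer(seq_len(B), (tdst - 1L) * B, "+"))
    src <- as.vector(outer(seq_len(B), (tdst + o - 1L) * B, "+"))
    out[dst, ] <- M[src, ]
  }
  out
}

## ---- linear ----------------------------------------------------------------

linear_fwd <- function(X, W, b) {
  list(out = X %*% W + bcast_row(b, nrow(X)), X = X)
}

linear_bwd <- function(dY, cache, W) {
  list(dX = dY %*% t(W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

## ---- multi-branch temporal convolution embedding ---------------------------
#
# Each branch k applies a same-padded 1-D convolution along time with kernel
# size k; branch outputs (each d_model / n_branches channels) are concatenated
# so the embedding expands the channel dimension and never reduces it.
# Branch weights are stored as a (k * C_in, C_out) matrix over the stacked
# shifted inputs. Encoder embeddings use centered windows (offsets
# -(k-1)/2 .. (k-1)/2); decoder output embeddings must be causal (offsets
# -(k-1) .. 0) so position i never sees later previous-growth days, keeping
# the look-ahead guarantee end to end.

conv_offsets <- function(k, causal) {
  if (causal) -(k - 1L):0L else -((k - 1L) %/% 2L):((k - 1L) %/% 2L)
}

conv_branch_fwd <- function(X, W, b, k, B, T, causal = FALSE) {
  offs <- conv_offsets(k, causal)
  Xcat <- do.call(cbind, lapply(offs, function(o) shift_time(X, B, T, o)))
  list(out = Xcat %*% W + bcast_row(b, nrow(X)), Xcat = Xcat)
}

conv_branch_bwd <- function(dY, cache, W, k, B, T, Cin, need_dx = FALSE,
                            causal = FALSE) {
  dW <- crossprod(cache$Xcat, dY)
  db <- colSums(dY)
  dX <- NULL
  if (need_dx) {
    dXcat <- dY %*% t(W)
    dX <- 0
    offs <- conv_offsets(k, causal)
    for (i in seq_along(offs)) {
      blk <- dXcat[, ((i - 1L) * Cin + 1L):(i * Cin), drop = FALSE]
      dX <- dX + shift_time(blk, B, T, -offs[i])
    }
  }
  list(dX = dX, dW = dW, db = db)
}

## ---- normalization ---------------------------------------------------------

batchnorm_fwd <- function(X, gamma, beta, run, train, momentum = 0.1,
                          eps = 1e-5) {
  if (train) {
    mu <- colMeans(X)
    v <- colMeans(X * X) - mu^2
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * v
  } else {
    mu <- run$mean; v <- run$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (X - bcast_row(mu, nrow(X))) * bcast_row(inv, nrow(X))
  list(out = xhat * bcast_row(gamma, nrow(X)) + bcast_row(beta, nrow(X)),
       xhat = xhat, inv = inv, train = train)
}

batchnorm_bwd <- function(dY, cache, gamma) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * bcast_row(gamma, n)
  if (cache$train) {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * cache$xhat)
    dX <- (dxhat - bcast_row(m1, n) - cache$xhat * bcast_row(m2, n)) *
      bcast_row(cache$inv, n)
  } else {
    dX <- dxhat * bcast_row(cache$inv, n)
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

layernorm_fwd <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  v <- rowMeans(X * X) - mu^2
  inv <- 1 / sqrt(v + eps)
  xhat <- (X - mu) * inv
  list(out = xhat * bcast_row(gamma, nrow(X)) + bcast_row(beta, nrow(X)),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dY, cache, gamma) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * bcast_row(gamma, n)
  dX <- (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat)) *
    cache$inv
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

## ---- dropout and activations ----------------------------------------------

dropout_fwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(out = X, mask = NULL))
  mask <- matrix(stats::rbinom(length(X), 1L, 1 - p), nrow(X)) / (1 - p)
  list(out = X * mask, mask = mask)
}

dropout_bwd <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

relu_fwd <- function(X) list(out = pmax(X, 0), pos = X > 0)
relu_bwd <- function(dY, cache) dY * cache$pos

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- positional encoding and masks ----------------------------------------

#' Sinusoidal positional encoding
#'
#' The standard deterministic transformer code: position `pos` (0-based) gets
#' `sin(pos / 10000^(2i/d))` in even-indexed and `cos(...)` in odd-indexed
#' dimensions, marking each step's position in the fixed-length window.
#'
#' @param steps Number of positions (>= 1).
#' @param d_model Embedding width (even).
#' @return `(steps, d_model)` matrix with values in \[-1, 1\].
#' @export
#' @examples
#' positional_encoding(4, 8)[1, ]  # position 0: alternating 0, 1
positional_encoding <- function(steps, d_model) {
  stopifnot(steps >= 1, d_model >= 2, d_model %% 2 == 0)
  pos <- 0:(steps - 1L)
  pe <- matrix(0, steps, d_model)
  for (i in 0:(d_model / 2 - 1L)) {
    freq <- 1 / 10000^(2 * i / d_model)
    pe[, 2L * i + 1L] <- sin(pos * freq)
    pe[, 2L * i + 2L] <- cos(pos * freq)
  }
  pe
}

#' Look-ahead (causal) visibility mask
#'
#' Query position i may attend only to key positions j <= i, enforcing
#' day-wise causality in the decoder self-attention. No padding mask is used
#' anywhere: all windows have fixed length.
#'
#' @param steps Sequence length L.
#' @return `(L, L)` logical matrix; `TRUE` where attention is permitted
#'   (lower triangle including the diagonal).
#' @export
look_ahead_mask <- function(steps) {
  stopifnot(steps >= 1)
  outer(seq_len(steps), seq_len(steps), ">=")
}

## ---- multi-head scaled dot-product attention -------------------------------
#
# Fused projection + attention + output mix. Qin is (B*Tq, d); Kin/Vin are a
# single (B*Tk, d) source (self-attention: the same tensor as Qin;
# cross-attention: the encoder memory). `mask` is a (Tq, Tk) logical
# visibility matrix or NULL. Attention weights are cached per (head, sample)
# for the backward pass and for inspection.

mha_core_fwd <- function(Qin, KVin, p, prefix, B, Tq, Tk, H, mask = NULL) {
  d <- ncol(p[[paste0(prefix, "_Wq")]])
  dh <- d %/% H
  Q <- Qin %*% p[[paste0(prefix, "_Wq")]] +
    bcast_row(p[[paste0(prefix, "_bq")]], nrow(Qin))
  K <- KVin %*% p[[paste0(prefix, "_Wk")]] +
    bcast_row(p[[paste0(prefix, "_bk")]], nrow(KVin))
  V <- KVin %*% p[[paste0(prefix, "_Wv")]] +
    bcast_row(p[[paste0(prefix, "_bv")]], nrow(KVin))
  A <- array(0, c(Tq, Tk, H, B))
  concat <- matrix(0, nrow(Qin), d)
  scale <- 1 / sqrt(dh)
  for (b in seq_len(B)) {
    iq <- rows_of(b, B, Tq); ik <- rows_of(b, B, Tk)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Q[iq, cols, drop = FALSE],
                      K[ik, cols, drop = FALSE]) * scale
      if (!is.null(mask)) S[!mask] <- -Inf
      S <- S - apply(S, 1, max)
      E <- exp(S)
      Ab <- E / rowSums(E)
      A[, , h, b] <- Ab
      concat[iq, cols] <- Ab %*% V[ik, cols, drop = FALSE]
    }
  }
  out <- concat %*% p[[paste0(prefix, "_Wo")]] +
    bcast_row(p[[paste0(prefix, "_bo")]], nrow(Qin))
  list(out = out, Q = Q, K = K, V = V, A = A, concat = concat,
       Qin = Qin, KVin = KVin)
}

mha_core_bwd <- function(dOut, cache, p, prefix, B, Tq, Tk, H, G) {
  d <- ncol(cache$Q); dh <- d %/% H
  scale <- 1 / sqrt(dh)
  g_add(G, paste0(prefix, "_Wo"), crossprod(cache$concat, dOut))
  g_add(G, paste0(prefix, "_bo"), colSums(dOut))
  dConcat <- dOut %*% t(p[[paste0(prefix, "_Wo")]])
  dQ <- matrix(0, nrow(cache$Q), d)
  dK <- matrix(0, nrow(cache$K), d)
  dV <- matrix(0, nrow(cache$V), d)
  for (b in seq_len(B)) {
    iq <- rows_of(b, B, Tq); ik <- rows_of(b, B, Tk)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Ab <- cache$A[, , h, b]
      if (Tq == 1L) Ab <- matrix(Ab, 1L, Tk)
      dOh <- dConcat[iq, cols, drop = FALSE]
      Vb <- cache$V[ik, cols, drop = FALSE]
      dA <- tcrossprod(dOh, Vb)
      dV[ik, cols] <- dV[ik, cols] + crossprod(Ab, dOh)
      dS <- Ab * (dA - rowSums(dA * Ab))          # softmax jacobian, rowwise
      dQ[iq, cols] <- dS %*% cache$K[ik, cols, drop = FALSE] * scale
      dK[ik, cols] <- dK[ik, cols] +
        crossprod(dS, cache$Q[iq, cols, drop = FALSE]) * scale
    }
  }
  g_add(G, paste0(prefix, "_Wq"), crossprod(cache$Qin, dQ))
  g_add(G, paste0(prefix, "_bq"), colSums(dQ))
  g_add(G, paste0(prefix, "_Wk"), crossprod(cache$KVin, dK))
  g_add(G, paste0(prefix, "_bk"), colSums(dK))
  g_add(G, paste0(prefix, "_Wv"), crossprod(cache$KVin, dV))
  g_add(G, paste0(prefix, "_bv"), colSums(dV))
  list(dQin = dQ %*% t(p[[paste0(prefix, "_Wq")]]),
       dKVin = dK %*% t(p[[paste0(prefix, "_Wk")]]) +
         dV %*% t(p[[paste0(prefix, "_Wv")]]))
}

#' Multi-head scaled dot-product attention (single sequence)
#'
#' Functional form for inspection and testing: splits `d_model` into
#' `n_heads` heads, computes `softmax(Q K' / sqrt(d_head))` per head with an
#' optional visibility mask, mixes the values and concatenates the heads.
#' With the default identity projections the call exposes the bare attention
#' arithmetic; supply a `weights` list (`Wq`, `Wk`, `Wv`, `Wo`, biases
#' optional) for learned projections.
#'
#' @param queries `(Tq, d)` matrix.
#' @param keys,values `(Tk, d)` matrices (the same source sequence).
#' @param n_heads Number of heads (must divide d).
#' @param mask Optional `(Tq, Tk)` logical visibility matrix, e.g.
#'   [look_ahead_mask()]. Masked weights are exactly zero.
#' @param weights Optional list of projection matrices; identity by default.
#' @return List with `output` (`(Tq, d)`) and `weights`: the attention array
#'   `(n_heads, Tq, Tk)`, rows summing to 1.
#' @export
multi_head_attention <- function(queries, keys, values, n_heads = 1L,
                                 mask = NULL, weights = NULL) {
  d <- ncol(queries)
  if (d %% n_heads != 0) stop("d_model must be divisible by n_heads")
  if (ncol(keys) != d || ncol(values) != d)
    stop("queries, keys and values must share the same width")
  if (nrow(keys) != nrow(values))
    stop("keys and values must share the same length")
  ident <- diag(d); zero <- numeric(d)
  w <- list(Wq = ident, Wk = ident, Wv = ident, Wo = ident,
            bq = zero, bk = zero, bv = zero, bo = zero)
  if (!is.null(weights)) w[names(weights)] <- weights
  Q <- queries %*% w$Wq + bcast_row(w$bq, nrow(queries))
  K <- keys %*% w$Wk + bcast_row(w$bk, nrow(keys))
  V <- values %*% w$Wv + bcast_row(w$bv, nrow(values))
  dh <- d %/% n_heads
  Tq <- nrow(queries); Tk <- nrow(keys)
  A <- array(0, c(n_heads, Tq, Tk))
  concat <- matrix(0, Tq, d)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
    if (!is.null(mask)) S[!mask] <- -Inf
    S <- S - apply(S, 1, max)
    E <- exp(S)
    Ah <- E / rowSums(E)
    A[h, , ] <- Ah
    concat[, cols] <- Ah %*% V[, cols, drop = FALSE]
  }
  list(output = concat %*% w$Wo + bcast_row(w$bo, Tq), weights = A)
}

## ---- gradient store --------------------------------------------------------

g_new <- function() new.env(parent = emptyenv())

g_add <- function(G, name, val) {
  if (is.null(G[[name]])) G[[name]] <- val else G[[name]] <- G[[name]] + val
  invisible(NULL)
}
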