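#' Model architecture configuration
#'
#' Hyperparameters of the attention crop model: a shared encoder over the
#' hourly feature window (24 * memory_length steps) and one structurally
#' identical decoder per factor group. Defaults are deliberately small so the
#' full train/simulate/evaluate cycle runs on a desktop CPU.
#'
#' @param memory_length Window length L in days; the encoder receives
#'   `24 * L` hourly rows and each decoder emits L daily rows.
#' @param d_model Embedding width (divisible by `n_heads` and by
#'   `length(kernels)`).
#' @param n_heads Attention heads.
#' @param n_encoder_blocks,n_decoder_blocks Numbers of attention blocks.
#' @param kernels Odd kernel sizes of the parallel convolution branches in
#'   the input/output embeddings.
#' @param ff_width Width of the position-wise feed-forward layers.
#' @param dropout Dropout rate applied after the embeddings during training.
#' @param decoder_map Named list mapping decoder names to disjoint factor
#'   index sets covering all factors; see [default_decoder_map()].
#' @param factor_names Names of the growth factors (defines n_factors).
#' @param n_features Number of encoder input features (7).
#' @param feature_mask Logical vector over the input features; `FALSE`
#'   columns are zeroed before embedding (used by input ablations).
#' @param use_gate Keep the input gate blending encoded memory with the
#'   projected raw features (`FALSE` removes it; structural ablation).
#' @param loss_mode `"multitask"` (six decoder losses + two vegetative
#'   conservation losses), `"decoders_only"` (six terms) or `"single"` (one
#'   pooled mean-squared-error term).
#' @param seed Seed for parameter initialization.
#' @return List of class `attncrop_config`.
#' @export
attncrop_config <- function(memory_length = 7L, d_model = 64L, n_heads = 4L,
                            n_encoder_blocks = 2L, n_decoder_blocks = 2L,
                            kernels = c(1L, 3L, 5L, 7L), ff_width = 128L,
                            dropout = 0, decoder_map = default_decoder_map(),
                            factor_names = crop_factors()$name,
                            n_features = 7L,
                            feature_mask = rep(TRUE, n_features),
                            use_gate = TRUE,
                            loss_mode = c("multitask", "decoders_only",
                                          "single"),
                            seed = 1L) {
  loss_mode <- match.arg(loss_mode)
  if (memory_length < 1L) stop("memory_length must be >= 1")
  if (d_model %% n_heads != 0)
    stop("d_model must be divisible by n_heads")
  if (d_model %% length(kernels) != 0)
    stop("d_model (", d_model, ") must be divisible by the number of ",
         "convolution branches (", length(kernels), ")")
  if (any(kernels %% 2 == 0)) stop("kernel sizes must be odd")
  if (length(feature_mask) != n_features)
    stop("feature_mask must have length n_features")
  check_decoder_map(decoder_map, length(factor_names))
  structure(list(memory_length = as.integer(memory_length),
                 d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 n_encoder_blocks = as.integer(n_encoder_blocks),
                 n_decoder_blocks = as.integer(n_decoder_blocks),
                 kernels = as.integer(kernels),
                 ff_width = as.integer(ff_width), dropout = dropout,
                 decoder_map = decoder_map, factor_names = factor_names,
                 n_features = as.integer(n_features),
                 feature_mask = feature_mask, use_gate = use_gate,
                 loss_mode = loss_mode, seed = as.integer(seed)),
            class = "attncrop_config")
}

glorot <- function(nin, nout, nr = nin, nc = nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# parameter shape catalogue: named list of c(nrow, ncol) / length-1 for vectors
param_shapes <- function(cfg) {
  d <- cfg$d_model
  nb <- length(cfg$kernels)
  wb <- d %/% nb
  sh <- list()
  emb <- function(prefix, cin) {
    for (i in seq_along(cfg$kernels))
      sh[[paste0(prefix, "_emb_k", i, "_W")]] <<- c(cfg$kernels[i] * cin, wb)
    for (i in seq_along(cfg$kernels))
      sh[[paste0(prefix, "_emb_k", i, "_b")]] <<- wb
    sh[[paste0(prefix, "_emb_bn_gamma")]] <<- d
    sh[[paste0(prefix, "_emb_bn_beta")]] <<- d
  }
  att <- function(prefix) {
    for (w in c("Wq", "Wk", "Wv", "Wo")) sh[[paste0(prefix, "_", w)]] <<- c(d, d)
    for (b in c("bq", "bk", "bv", "bo")) sh[[paste0(prefix, "_", b)]] <<- d
  }
  ln <- function(prefix) {
    sh[[paste0(prefix, "_gamma")]] <<- d; sh[[paste0(prefix, "_beta")]] <<- d
  }
  ff <- function(prefix) {
    sh[[paste0(prefix, "_W1")]] <<- c(d, cfg$ff_width)
    sh[[paste0(prefix, "_b1")]] <<- cfg$ff_width
    sh[[paste0(prefix, "_W2")]] <<- c(cfg$ff_width, d)
    sh[[paste0(prefix, "_b2")]] <<- d
  }
  emb("enc", cfg$n_features)
  for (l in seq_len(cfg$n_encoder_blocks)) {
    pre <- paste0("enc", l)
    att(paste0(pre, "_att")); ln(paste0(pre, "_ln1"))
    ff(paste0(pre, "_ff")); ln(paste0(pre, "_ln2"))
  }
  if (cfg$use_gate) {
    sh$gate_proj_W <- c(cfg$n_features, d); sh$gate_proj_b <- d
    sh$gate_W <- c(2L * d, d); sh$gate_b <- d
  }
  nf <- length(cfg$factor_names)
  for (nm in names(cfg$decoder_map)) {
    emb(paste0("dec_", nm), nf)
    for (l in seq_len(cfg$n_decoder_blocks)) {
      pre <- paste0("dec_", nm, l)
      att(paste0(pre, "_self")); ln(paste0(pre, "_ln1"))
      att(paste0(pre, "_cross")); ln(paste0(pre, "_ln2"))
      ff(paste0(pre, "_ff")); ln(paste0(pre, "_ln3"))
    }
    k_d <- length(cfg$decoder_map[[nm]])
    sh[[paste0("dec_", nm, "_head_W")]] <- c(d, k_d)
    sh[[paste0("dec_", nm, "_head_b")]] <- k_d
  }
  sh
}

# initialize all parameters (Glorot uniform weights, zero biases, unit gains)
init_params <- function(cfg) {
  sh <- param_shapes(cfg)
  with_seed(cfg$seed, {
    p <- lapply(names(sh), function(nm) {
      s <- sh[[nm]]
      if (length(s) == 2L) {
        if (grepl("_(gamma)$", nm)) stop("shape bug")
        glorot(s[1], s[2])
      } else if (grepl("_gamma$", nm)) rep(1, s)
      else rep(0, s)
    })
    names(p) <- names(sh)
    p
  })
}

# fresh running-statistics store for the batch-normalized embeddings
init_norm_state <- function(cfg) {
  st <- new.env(parent = emptyenv())
  for (nm in c("enc", paste0("dec_", names(cfg$decoder_map)))) {
    st[[paste0(nm, "_emb_bn")]] <- list(mean = rep(0, cfg$d_model),
                                        var = rep(1, cfg$d_model))
  }
  st
}

## ---- forward ---------------------------------------------------------------

embed_fwd <- function(X, p, prefix, cfg, B, T, cin, norm, train,
                      causal = FALSE) {
  nb <- length(cfg$kernels)
  branches <- vector("list", nb)
  outs <- vector("list", nb)
  for (i in seq_len(nb)) {
    br <- conv_branch_fwd(X, p[[paste0(prefix, "_emb_k", i, "_W")]],
                          p[[paste0(prefix, "_emb_k", i, "_b")]],
                          cfg$kernels[i], B, T, causal = causal)
    branches[[i]] <- br
    outs[[i]] <- br$out
  }
  E <- do.call(cbind, outs)
  key <- paste0(prefix, "_emb_bn")
  run <- norm[[key]]
  runenv <- as.environment(run)
  bn <- batchnorm_fwd(E, p[[paste0(key, "_gamma")]],
                      p[[paste0(key, "_beta")]], runenv, train)
  if (train) norm[[key]] <- list(mean = runenv$mean, var = runenv$var)
  pe <- positional_encoding(T, cfg$d_model)
  out0 <- bn$out + pe[rep(seq_len(T), each = B), , drop = FALSE]
  dr <- dropout_fwd(out0, cfg$dropout, train)
  list(out = dr$out, branches = branches, bn = bn, dr = dr)
}

embed_bwd <- function(dY, cache, p, prefix, cfg, B, T, cin, G,
                      causal = FALSE) {
  dY <- dropout_bwd(dY, cache$dr)
  key <- paste0(prefix, "_emb_bn")
  bb <- batchnorm_bwd(dY, cache$bn, p[[paste0(key, "_gamma")]])
  g_add(G, paste0(key, "_gamma"), bb$dgamma)
  g_add(G, paste0(key, "_beta"), bb$dbeta)
  nb <- length(cfg$kernels)
  wb <- cfg$d_model %/% nb
  for (i in seq_len(nb)) {
    cols <- ((i - 1L) * wb + 1L):(i * wb)
    cb <- conv_branch_bwd(bb$dX[, cols, drop = FALSE], cache$branches[[i]],
                          p[[paste0(prefix, "_emb_k", i, "_W")]],
                          cfg$kernels[i], B, T, cin, need_dx = FALSE,
                          causal = causal)
    g_add(G, paste0(prefix, "_emb_k", i, "_W"), cb$dW)
    g_add(G, paste0(prefix, "_emb_k", i, "_b"), cb$db)
  }
  invisible(NULL)
}

ffn_fwd <- function(X, p, prefix) {
  l1 <- linear_fwd(X, p[[paste0(prefix, "_W1")]], p[[paste0(prefix, "_b1")]])
  r <- relu_fwd(l1$out)
  l2 <- linear_fwd(r$out, p[[paste0(prefix, "_W2")]], p[[paste0(prefix, "_b2")]])
  list(out = l2$out, l1 = l1, r = r, l2 = l2)
}

ffn_bwd <- function(dY, cache, p, prefix, G) {
  b2 <- linear_bwd(dY, cache$l2, p[[paste0(prefix, "_W2")]])
  g_add(G, paste0(prefix, "_W2"), b2$dW); g_add(G, paste0(prefix, "_b2"), b2$db)
  dr <- relu_bwd(b2$dX, cache$r)
  b1 <- linear_bwd(dr, cache$l1, p[[paste0(prefix, "_W1")]])
  g_add(G, paste0(prefix, "_W1"), b1$dW); g_add(G, paste0(prefix, "_b1"), b1$db)
  b1$dX
}

# residual + post-norm helper: y = LN(x + sub)
resnorm_fwd <- function(x, sub, p, prefix) {
  ln <- layernorm_fwd(x + sub, p[[paste0(prefix, "_gamma")]],
                      p[[paste0(prefix, "_beta")]])
  ln
}

resnorm_bwd <- function(dY, cache, p, prefix, G) {
  lb <- layernorm_bwd(dY, cache, p[[paste0(prefix, "_gamma")]])
  g_add(G, paste0(prefix, "_gamma"), lb$dgamma)
  g_add(G, paste0(prefix, "_beta"), lb$dbeta)
  lb$dX   # gradient for both the residual branch and the sublayer output
}

# Full model forward pass.
#   X: (B*24L, n_features) standardized encoder input
#   P: (B*L, n_factors) standardized previous-growth input
# Returns per-decoder prediction matrices (B*L, k_d) in standardized space,
# plus caches for the backward pass, attention arrays and last-hidden states.
model_forward <- function(p, cfg, X, P, B, norm, train = FALSE,
                          capture_attention = FALSE) {
  L <- cfg$memory_length
  Te <- 24L * L
  H <- cfg$n_heads
  if (nrow(X) != B * Te) stop("encoder input must have 24 * memory_length ",
                              "rows per sample")
  if (nrow(P) != B * L) stop("previous growth must have memory_length rows ",
                             "per sample")
  if (!all(cfg$feature_mask))
    X[, !cfg$feature_mask] <- 0
  cache <- list(X = X, P = P, B = B)
  # encoder
  emb <- embed_fwd(X, p, "enc", cfg, B, Te, cfg$n_features, norm, train)
  x <- emb$out
  encb <- vector("list", cfg$n_encoder_blocks)
  for (l in seq_len(cfg$n_encoder_blocks)) {
    pre <- paste0("enc", l)
    at <- mha_core_fwd(x, x, p, paste0(pre, "_att"), B, Te, Te, H, mask = NULL)
    n1 <- resnorm_fwd(x, at$out, p, paste0(pre, "_ln1"))
    ffc <- ffn_fwd(n1$out, p, paste0(pre, "_ff"))
    n2 <- resnorm_fwd(n1$out, ffc$out, p, paste0(pre, "_ln2"))
    encb[[l]] <- list(at = at, n1 = n1, ff = ffc, n2 = n2)
    x <- n2$out
  }
  cache$emb <- emb; cache$encb <- encb
  # input gate
  if (cfg$use_gate) {
    proj <- linear_fwd(X, p$gate_proj_W, p$gate_proj_b)
    cat2 <- cbind(proj$out, x)
    z <- cat2 %*% p$gate_W + bcast_row(p$gate_b, nrow(X))
    g <- sigmoid(z)
    mem <- g * x + (1 - g) * proj$out
    cache$gate <- list(proj = proj, cat2 = cat2, g = g, enc_out = x)
  } else {
    mem <- x
  }
  cache$mem <- mem
  # decoders
  self_mask <- look_ahead_mask(L)
  preds <- list(); decc <- list(); attn <- list(); hidden <- list()
  nf <- length(cfg$factor_names)
  for (nm in names(cfg$decoder_map)) {
    demb <- embed_fwd(P, p, paste0("dec_", nm), cfg, B, L, nf, norm,
                      train, causal = TRUE)
    y <- demb$out
    blocks <- vector("list", cfg$n_decoder_blocks)
    for (l in seq_len(cfg$n_decoder_blocks)) {
      pre <- paste0("dec_", nm, l)
      sa <- mha_core_fwd(y, y, p, paste0(pre, "_self"), B, L, L, H,
                         mask = self_mask)
      n1 <- resnorm_fwd(y, sa$out, p, paste0(pre, "_ln1"))
      ca <- mha_core_fwd(n1$out, mem, p, paste0(pre, "_cross"), B, L, Te, H,
                         mask = NULL)
      n2 <- resnorm_fwd(n1$out, ca$out, p, paste0(pre, "_ln2"))
      ffc <- ffn_fwd(n2$out, p, paste0(pre, "_ff"))
      n3 <- resnorm_fwd(n2$out, ffc$out, p, paste0(pre, "_ln3"))
      blocks[[l]] <- list(sa = sa, n1 = n1, ca = ca, n2 = n2, ff = ffc,
                          n3 = n3)
      if (capture_attention) {
        attn[[paste0(nm, "_b", l, "_self")]] <-
          list(decoder = nm, block = l, kind = "self", weights = sa$A)
        attn[[paste0(nm, "_b", l, "_cross")]] <-
          list(decoder = nm, block = l, kind = "cross", weights = ca$A)
      }
      y <- n3$out
    }
    head <- linear_fwd(y, p[[paste0("dec_", nm, "_head_W")]],
                       p[[paste0("dec_", nm, "_head_b")]])
    preds[[nm]] <- head$out
    hidden[[nm]] <- y
    decc[[nm]] <- list(emb = demb, blocks = blocks, head = head)
  }
  cache$dec <- decc
  list(preds = preds, cache = cache, attention = attn, hidden = hidden)
}

# Backward pass: dpreds is a named list of (B*L, k_d) gradients.
# Returns the gradient store G (environment of parameter gradients).
model_backward <- function(dpreds, fw, p, cfg) {
  cache <- fw$cache
  B <- cache$B
  L <- cfg$memory_length
  Te <- 24L * L
  H <- cfg$n_heads
  nf <- length(cfg$factor_names)
  G <- g_new()
  dmem <- matrix(0, B * Te, cfg$d_model)
  for (nm in names(cfg$decoder_map)) {
    dc <- cache$dec[[nm]]
    hb <- linear_bwd(dpreds[[nm]], dc$head, p[[paste0("dec_", nm, "_head_W")]])
    g_add(G, paste0("dec_", nm, "_head_W"), hb$dW)
    g_add(G, paste0("dec_", nm, "_head_b"), hb$db)
    dy <- hb$dX
    for (l in rev(seq_len(cfg$n_decoder_blocks))) {
      pre <- paste0("dec_", nm, l)
      bl <- dc$blocks[[l]]
      dn3 <- resnorm_bwd(dy, bl$n3, p, paste0(pre, "_ln3"), G)
      dff <- ffn_bwd(dn3, bl$ff, p, paste0(pre, "_ff"), G)
      dn2out <- dn3 + dff
      dn2 <- resnorm_bwd(dn2out, bl$n2, p, paste0(pre, "_ln2"), G)
      cb <- mha_core_bwd(dn2, bl$ca, p, paste0(pre, "_cross"), B, L, Te, H, G)
      dmem <- dmem + cb$dKVin
      dn1out <- dn2 + cb$dQin
      dn1 <- resnorm_bwd(dn1out, bl$n1, p, paste0(pre, "_ln1"), G)
      sb <- mha_core_bwd(dn1, bl$sa, p, paste0(pre, "_self"), B, L, L, H, G)
      dy <- dn1 + sb$dQin + sb$dKVin
    }
    embed_bwd(dy, dc$emb, p, paste0("dec_", nm), cfg, B, L, nf, G,
              causal = TRUE)
  }
  # gate
  if (cfg$use_gate) {
    gt <- cache$gate
    g <- gt$g
    denc <- dmem * g
    dproj <- dmem * (1 - g)
    dg <- dmem * (gt$enc_out - gt$proj$out)
    dz <- dg * g * (1 - g)
    g_add(G, "gate_W", crossprod(gt$cat2, dz))
    g_add(G, "gate_b", colSums(dz))
    dcat <- dz %*% t(p$gate_W)
    dproj <- dproj + dcat[, seq_len(cfg$d_model), drop = FALSE]
    denc <- denc + dcat[, cfg$d_model + seq_len(cfg$d_model), drop = FALSE]
    pb <- linear_bwd(dproj, gt$proj, p$gate_proj_W)
    g_add(G, "gate_proj_W", pb$dW)
    g_add(G, "gate_proj_b", pb$db)
    dx <- denc
  } else {
    dx <- dmem
  }
  # encoder blocks
  for (l in rev(seq_len(cfg$n_encoder_blocks))) {
    pre <- paste0("enc", l)
    bl <- cache$encb[[l]]
    dn2 <- resnorm_bwd(dx, bl$n2, p, paste0(pre, "_ln2"), G)
    dff <- ffn_bwd(dn2, bl$ff, p, paste0(pre, "_ff"), G)
    dn1out <- dn2 + dff
    dn1 <- resnorm_bwd(dn1out, bl$n1, p, paste0(pre, "_ln1"), G)
    ab <- mha_core_bwd(dn1, bl$at, p, paste0(pre, "_att"), B, Te, Te, H, G)
    dx <- dn1 + ab$dQin + ab$dKVin
  }
  embed_bwd(dx, cache$emb, p, "enc", cfg, B, Te, cfg$n_features, G)
  G
}

# total number of learned parameters, overall or per component prefix
count_params <- function(p, prefix = NULL) {
  nm <- names(p)
  if (!is.null(prefix)) nm <- nm[startsWith(nm, prefix)]
  sum(vapply(p[nm], length, 1L))
}
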