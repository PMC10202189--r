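#' Fit standardization statistics on training windows
#'
#' Computes per-feature and per-factor location (mean) and scale (SD) from
#' the training split only; validation and simulation data are transformed
#' with these same statistics. Zero-variance columns get scale 1 with a
#' warning (e.g. a constant organ count).
#'
#' @param samples List of window samples (the `train` element of
#'   [make_training_windows()] output).
#' @return List of class `crop_scaler` with `feat_mean`, `feat_sd`,
#'   `fac_mean`, `fac_sd`.
#' @export
fit_scaler <- function(samples) {
  if (length(samples) < 2L) stop("need at least two samples to fit a scaler")
  feats <- do.call(rbind, lapply(samples, `[[`, "features"))
  facs <- do.call(rbind, lapply(samples, function(s) rbind(s$prev, s$target)))
  fix <- function(s, what) {
    if (any(s == 0)) {
      warning("zero-variance ", what, " column(s): ",
              paste(names(s)[s == 0], collapse = ", "), "; scale set to 1")
      s[s == 0] <- 1
    }
    s
  }
  structure(list(
    feat_mean = colMeans(feats),
    feat_sd = fix(apply(feats, 2, stats::sd), "feature"),
    fac_mean = colMeans(facs),
    fac_sd = fix(apply(facs, 2, stats::sd), "factor")),
    class = "crop_scaler")
}

#' Apply or invert a fitted scaler
#'
#' `scale_transform()` maps natural units to z-scores; `scale_invert()` is
#' its exact inverse.
#'
#' @param x Matrix (columns = features or factors) or vector.
#' @param scaler A [fit_scaler()] result.
#' @param what `"features"` or `"factors"`.
#' @return Transformed matrix of the same shape.
#' @export
scale_transform <- function(x, scaler, what = c("features", "factors")) {
  what <- match.arg(what)
  m <- if (what == "features") scaler$feat_mean else scaler$fac_mean
  s <- if (what == "features") scaler$feat_sd else scaler$fac_sd
  if (is.null(dim(x))) (x - m) / s
  else sweep(sweep(x, 2, m), 2, s, "/")
}

#' @rdname scale_transform
#' @export
scale_invert <- function(x, scaler, what = c("features", "factors")) {
  what <- match.arg(what)
  m <- if (what == "features") scaler$feat_mean else scaler$fac_mean
  s <- if (what == "features") scaler$feat_sd else scaler$fac_sd
  if (is.null(dim(x))) x * s + m
  else sweep(sweep(x, 2, s, "*"), 2, m, "+")
}

#' Assemble the multitask training loss
#'
#' In the default `"multitask"` mode the loss has eight terms: one mean
#' squared error per decoder (over its factors and the L days) plus two
#' consistency terms tying the predicted total vegetative fresh and dry
#' weight (leaf + stem + petiole) to the target totals. The total is the
#' unweighted arithmetic mean of the terms. `"decoders_only"` drops the two
#' conservation terms; `"single"` pools all factors into one MSE.
#'
#' @param predictions Named list of per-decoder prediction matrices
#'   `(rows, k_d)` as returned by the model (standardized space during
#'   training, but the arithmetic is scale-agnostic).
#' @param targets Matrix `(rows, n_factors)` of target values with columns in
#'   factor order.
#' @param cfg An [attncrop_config()] (supplies `decoder_map`, `factor_names`
#'   and `loss_mode`).
#' @param grad If `TRUE`, also return the gradient of the total loss with
#'   respect to each decoder's predictions.
#' @return Object of class `loss_breakdown`: list with `terms` (named,
#'   all >= 0), `total` (their mean) and optionally `dpreds`.
#' @export
assemble_loss <- function(predictions, targets, cfg, grad = FALSE) {
  dm <- cfg$decoder_map
  if (!setequal(names(predictions), names(dm)))
    stop("prediction decoder names do not match the decoder map")
  n_rows <- nrow(targets)
  for (nm in names(dm)) {
    if (!all(dim(predictions[[nm]]) == c(n_rows, length(dm[[nm]]))))
      stop("decoder '", nm, "' prediction shape does not match its factor set")
  }
  terms <- c()
  dpreds <- if (grad) lapply(predictions, function(m) matrix(0, nrow(m),
                                                             ncol(m)))
  fac <- cfg$factor_names
  if (cfg$loss_mode == "single") {
    err2 <- 0; n_el <- 0
    for (nm in names(dm)) {
      e <- predictions[[nm]] - targets[, dm[[nm]], drop = FALSE]
      err2 <- err2 + sum(e * e)
      n_el <- n_el + length(e)
    }
    terms <- c(mse = err2 / n_el)
    if (grad) for (nm in names(dm)) {
      e <- predictions[[nm]] - targets[, dm[[nm]], drop = FALSE]
      dpreds[[nm]] <- 2 * e / n_el
    }
  } else {
    for (nm in names(dm)) {
      e <- predictions[[nm]] - targets[, dm[[nm]], drop = FALSE]
      terms[nm] <- mean(e * e)
    }
    n_terms <- length(dm)
    veg <- list()
    if (cfg$loss_mode == "multitask") {
      for (kind in c("fw", "dw")) {
        want <- if (kind == "fw") veg_fw_factors() else veg_dw_factors()
        idx <- match(want, fac)
        if (anyNA(idx))
          stop("conservation loss needs factors ",
               paste(want, collapse = ", "), " in factor_names")
        ps <- 0; ts <- 0
        parts <- list()
        for (j in idx) {
          nm <- names(dm)[vapply(dm, function(v) j %in% v, TRUE)]
          col <- match(j, dm[[nm]])
          parts[[length(parts) + 1L]] <- list(nm = nm, col = col)
          ps <- ps + predictions[[nm]][, col]
          ts <- ts + targets[, j]
        }
        terms[paste0("veg_", kind)] <- mean((ps - ts)^2)
        veg[[kind]] <- list(parts = parts, e = ps - ts)
      }
      n_terms <- n_terms + 2L
    }
    if (grad) {
      for (nm in names(dm)) {
        e <- predictions[[nm]] - targets[, dm[[nm]], drop = FALSE]
        dpreds[[nm]] <- 2 * e / length(e) / n_terms
      }
      for (kind in names(veg)) {
        v <- veg[[kind]]
        for (pp in v$parts) {
          dpreds[[pp$nm]][, pp$col] <- dpreds[[pp$nm]][, pp$col] +
            2 * v$e / n_rows / n_terms
        }
      }
    }
  }
  out <- list(terms = terms, total = mean(terms))
  if (grad) out$dpreds <- dpreds
  class(out) <- "loss_breakdown"
  out
}

# stack a list of samples into batch matrices (rows sample-major)
stack_batch <- function(samples, scaler, cfg) {
  B <- length(samples)
  L <- cfg$memory_length
  Te <- 24L * L
  nf <- length(cfg$factor_names)
  X <- matrix(0, B * Te, cfg$n_features)
  P <- Tg <- matrix(0, B * L, nf)
  for (b in seq_len(B)) {
    X[rows_of(b, B, Te), ] <- scale_transform(samples[[b]]$features, scaler,
                                              "features")
    P[rows_of(b, B, L), ] <- scale_transform(samples[[b]]$prev, scaler,
                                             "factors")
    Tg[rows_of(b, B, L), ] <- scale_transform(samples[[b]]$target, scaler,
                                              "factors")
  }
  list(X = X, P = P, target = Tg, B = B)
}

# forward + loss over a sample set in evaluation mode, batched
eval_loss <- function(samples, p, cfg, scaler, norm, batch_size = 32L) {
  if (!length(samples)) return(NA_real_)
  tot <- 0; n <- 0
  for (i in seq(1L, length(samples), by = batch_size)) {
    chunk <- samples[i:min(i + batch_size - 1L, length(samples))]
    ba <- stack_batch(chunk, scaler, cfg)
    fw <- model_forward(p, cfg, ba$X, ba$P, ba$B, norm, train = FALSE)
    lb <- assemble_loss(fw$preds, ba$target, cfg)
    tot <- tot + lb$total * length(chunk)
    n <- n + length(chunk)
  }
  tot / n
}

#' Train the attention crop model
#'
#' Seeded, mini-batched Adam descent on the averaged multitask loss with
#' teacher forcing: the decoder input is the observed (augmented) previous
#' growth, never the model's own output. Cumulative input features keep the
#' dataset's own values during training; guidance replacement happens only at
#' simulation time. The state with the lowest validation total loss is
#' returned.
#'
#' @param windows A [make_training_windows()] result.
#' @param cfg An [attncrop_config()].
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate (moment decays 0.9/0.999).
#' @param patience Early-stopping patience in epochs on the validation total
#'   (`Inf` disables early stopping).
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @param verbose Print per-epoch losses.
#' @return List with `params`, `norm` (normalization running statistics),
#'   `scaler`, `config`, `trace` (per-epoch data.frame: the loss terms,
#'   `total` and `val_total`) and `best_epoch`.
#' @export
train_attncrop <- function(windows, cfg, epochs = 30L, batch_size = 32L,
                           lr = 1e-3, patience = Inf, seed = cfg$seed,
                           verbose = FALSE) {
  stopifnot(inherits(windows, "crop_windows"))
  if (!length(windows$train)) stop("empty training set")
  if (windows$memory_length != cfg$memory_length)
    stop("windows were built with memory_length ", windows$memory_length,
         " but the config says ", cfg$memory_length)
  scaler <- fit_scaler(windows$train)
  p <- init_params(cfg)
  norm <- init_norm_state(cfg)
  m <- lapply(p, function(x) x * 0)
  v <- lapply(p, function(x) x * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  trace <- NULL
  best <- list(val = Inf, params = p, norm = as.list(norm), epoch = 0L)
  wait <- 0L
  with_seed(seed, {
    n_tr <- length(windows$train)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_tr)
      term_sum <- NULL; nb <- 0L
      for (i in seq(1L, n_tr, by = batch_size)) {
        idx <- ord[i:min(i + batch_size - 1L, n_tr)]
        ba <- stack_batch(windows$train[idx], scaler, cfg)
        fw <- model_forward(p, cfg, ba$X, ba$P, ba$B, norm, train = TRUE)
        lb <- assemble_loss(fw$preds, ba$target, cfg, grad = TRUE)
        if (!is.finite(lb$total))
          stop("training diverged: non-finite loss at epoch ", ep,
               ", batch starting at sample ", i)
        G <- model_backward(lb$dpreds, fw, p, cfg)
        step <- step + 1L
        corr <- sqrt(1 - beta2^step) / (1 - beta1^step)
        for (nm in names(p)) {
          g <- G[[nm]]
          if (is.null(g)) next
          m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g
          v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g * g
          p[[nm]] <- p[[nm]] - lr * corr * m[[nm]] / (sqrt(v[[nm]]) + eps)
        }
        term_sum <- if (is.null(term_sum)) lb$terms else term_sum + lb$terms
        nb <- nb + 1L
      }
      terms <- term_sum / nb
      val <- eval_loss(windows$val, p, cfg, scaler, norm, batch_size)
      row <- as.data.frame(as.list(c(epoch = ep, terms,
                                     total = mean(terms), val_total = val)))
      trace <- if (is.null(trace)) row else rbind(trace, row)
      crit <- if (is.na(val)) mean(terms) else val
      if (crit < best$val) {
        best <- list(val = crit, params = p, norm = as.list(norm), epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f", ep, mean(terms),
                        val))
    }
  })
  norm_best <- new.env(parent = emptyenv())
  for (nm in names(best$norm)) norm_best[[nm]] <- best$norm[[nm]]
  list(params = best$params, norm = norm_best, scaler = scaler, config = cfg,
       trace = trace, best_epoch = best$epoch)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS container holding the configuration
#' snapshot, all learned parameters, normalization running statistics and the
#' scaler (simulation cannot run without it). Loading validates the parameter
#' set against the embedded configuration; a mismatched decoder map or
#' missing component is an error, never a silent reshape.
#'
#' @param model A fitted [attncrop] model (or [train_attncrop()] result).
#' @param path File path.
#' @return `load_checkpoint()` returns the model object.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(!is.null(model$params), !is.null(model$config))
  obj <- list(format = "attncrop-checkpoint", version = 1L,
              config = model$config, params = model$params,
              norm = as.list(model$norm), scaler = model$scaler,
              trace = model$trace, best_epoch = model$best_epoch)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint file not found: ", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt checkpoint: ", conditionMessage(e)))
  if (!identical(obj$format, "attncrop-checkpoint"))
    stop("not an attncrop checkpoint: ", path)
  if (is.null(obj$scaler))
    stop("checkpoint lacks scaler statistics; cannot simulate")
  sh <- param_shapes(obj$config)
  if (!setequal(names(sh), names(obj$params)))
    stop("checkpoint parameters do not match its configuration ",
         "(decoder map or architecture mismatch)")
  for (nm in names(sh)) {
    want <- sh[[nm]]
    got <- if (is.matrix(obj$params[[nm]])) dim(obj$params[[nm]])
           else length(obj$params[[nm]])
    if (!identical(as.integer(want), as.integer(got)))
      stop("checkpoint parameter '", nm, "' has wrong shape")
  }
  norm <- new.env(parent = emptyenv())
  for (nm in names(obj$norm)) norm[[nm]] <- obj$norm[[nm]]
  structure(list(params = obj$params, norm = norm, scaler = obj$scaler,
                 config = obj$config, trace = obj$trace,
                 best_epoch = obj$best_epoch, call = NULL),
            class = "attncrop")
}
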