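#' Fit an attention-based crop growth model
#'
#' Trains the full model -- convolutional input/output embeddings, positional
#' encoding, a shared multi-head attention encoder over the hourly feature
#' window, an input gate, and six multitask decoders (status, property, leaf,
#' stem, petiole, harvest) -- on teacher-forced training windows, minimizing
#' the averaged eight-term mean-squared-error loss (one term per decoder plus
#' two vegetative-conservation terms).
#'
#' @param windows Training windows from [make_training_windows()].
#' @param config An [attncrop_config()]; defaults to the small desk-scale
#'   architecture (L = 7 days, 64-wide embeddings, 4 heads, 2 + 2 blocks,
#'   kernel sizes 1/3/5/7).
#' @param epochs,batch_size,lr,patience,seed,verbose Passed to
#'   [train_attncrop()].
#' @return An object of class `attncrop` with components `params`, `norm`,
#'   `scaler`, `config`, `trace`, `best_epoch`, `call`. Methods: `print`,
#'   `summary`, `coef`, `predict`, `residuals`, `simulate`, `plot`.
#' @seealso [run_simulation()], [evaluate_simulation()], [save_checkpoint()]
#' @export
#' @examples
#' \donttest{
#' sc <- cultivation_scenario(n_days = 40, seed = 7)
#' env <- generate_environment(sc)
#' truth <- simulate_reference_growth(env, scenario = sc)
#' obs <- sample_destructive_observations(truth, n_dates = 4, seed = 8)
#' lab <- interpolate_growth_daily(obs)
#' w <- make_training_windows(list(list(env = env, labels = lab)),
#'                            memory_length = 3)
#' fit <- attncrop(w, attncrop_config(memory_length = 3, d_model = 16,
#'                                    n_heads = 2, n_encoder_blocks = 1,
#'                                    n_decoder_blocks = 1,
#'                                    kernels = c(1, 3), ff_width = 32),
#'                 epochs = 2)
#' fit
#' }
attncrop <- function(windows, config = attncrop_config(), epochs = 30L,
                     batch_size = 32L, lr = 1e-3, patience = Inf,
                     seed = config$seed, verbose = FALSE) {
  fit <- train_attncrop(windows, config, epochs = epochs,
                        batch_size = batch_size, lr = lr, patience = patience,
                        seed = seed, verbose = verbose)
  fit$call <- match.call()
  class(fit) <- "attncrop"
  fit
}

#' @export
print.attncrop <- function(x, ...) {
  cfg <- x$config
  cat("Attention-based crop growth model\n")
  if (!is.null(x$call)) {
    cat("Call: "); print(x$call)
  }
  cat(sprintf("  memory length: %d days (encoder input %d hourly steps)\n",
              cfg$memory_length, 24L * cfg$memory_length))
  cat(sprintf("  d_model %d, %d heads, %d encoder / %d decoder blocks\n",
              cfg$d_model, cfg$n_heads, cfg$n_encoder_blocks,
              cfg$n_decoder_blocks))
  cat(sprintf("  decoders (%d): %s\n", length(cfg$decoder_map),
              paste(names(cfg$decoder_map), collapse = ", ")))
  cat(sprintf("  parameters: %s\n",
              format(count_params(x$params), big.mark = ",")))
  if (!is.null(x$trace)) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  trained %d epochs; best epoch %d; final total loss %.5f",
                nrow(x$trace), x$best_epoch, last$total))
    if (!is.na(last$val_total))
      cat(sprintf(" (val %.5f)", last$val_total))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.attncrop <- function(object, ...) {
  cfg <- object$config
  comp <- c("enc", "gate", paste0("dec_", names(cfg$decoder_map)))
  counts <- vapply(comp, function(pf) count_params(object$params, pf), 1)
  out <- list(config = cfg, param_counts = counts,
              total_params = count_params(object$params),
              trace = object$trace, best_epoch = object$best_epoch)
  class(out) <- "summary.attncrop"
  out
}

#' @export
print.summary.attncrop <- function(x, ...) {
  cat("Parameters by component:\n")
  print(x$param_counts)
  cat("Total:", x$total_params, "\n")
  if (!is.null(x$trace)) {
    cat("\nLoss trace (last 5 epochs):\n")
    print(utils::tail(x$trace, 5), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.attncrop <- function(object, ...) object$params

#' Teacher-forced predictions on window samples
#'
#' One forward pass per window with observed previous growth as decoder
#' input (no recursion); predictions are returned in natural units.
#'
#' @param object A fitted [attncrop] model.
#' @param newdata A `crop_windows` object or a plain list of window samples;
#'   defaults to nothing (there is no stored training data).
#' @param ... Unused.
#' @return Matrix `(n_samples * L, n_factors)` of predictions in factor
#'   order, with attribute `samples` giving the sample index of each row.
#' @export
predict.attncrop <- function(object, newdata, ...) {
  samples <- if (inherits(newdata, "crop_windows"))
    c(newdata$train, newdata$val) else newdata
  if (!length(samples)) stop("no samples to predict")
  cfg <- object$config
  ba <- stack_batch(samples, object$scaler, cfg)
  fw <- model_forward(object$params, cfg, ba$X, ba$P, ba$B, object$norm,
                      train = FALSE)
  nf <- length(cfg$factor_names)
  out <- matrix(NA_real_, nrow(ba$target), nf,
                dimnames = list(NULL, cfg$factor_names))
  for (nm in names(cfg$decoder_map))
    out[, cfg$decoder_map[[nm]]] <- fw$preds[[nm]]
  out <- scale_invert(out, object$scaler, "factors")
  # rows are sample-major: row (b, t) at b + (t-1) * B
  attr(out, "samples") <- rep(seq_len(ba$B), times = cfg$memory_length)
  attr(out, "positions") <- rep(seq_len(cfg$memory_length), each = ba$B)
  out
}

#' @export
residuals.attncrop <- function(object, newdata, ...) {
  samples <- if (inherits(newdata, "crop_windows"))
    c(newdata$train, newdata$val) else newdata
  pred <- predict(object, samples)
  B <- length(samples)
  L <- object$config$memory_length
  tgt <- matrix(NA_real_, nrow(pred), ncol(pred))
  for (b in seq_len(B)) tgt[rows_of(b, B, L), ] <- samples[[b]]$target
  res <- tgt - pred
  attributes(res)[c("samples", "positions")] <-
    attributes(pred)[c("samples", "positions")]
  colnames(res) <- colnames(pred)
  res
}

#' Simulate crop growth with a fitted model
#'
#' S3 `simulate` method wrapping [run_simulation()]: recursive daily rollout
#' from initial growth factors and environment only. The rollout is
#' deterministic given the checkpoint, so `nsim` and `seed` are accepted for
#' interface compatibility but replicate runs are identical.
#'
#' @param object A fitted [attncrop] model.
#' @param nsim Number of trajectories (all identical; default 1).
#' @param seed Ignored (kept for the generic's signature).
#' @param env,init,n_days,guidance,sanitize See [run_simulation()].
#' @param ... Unused.
#' @return A `crop_simulation` data.frame (or a list of them if `nsim > 1`).
#' @export
simulate.attncrop <- function(object, nsim = 1, seed = NULL, env, init,
                              n_days, guidance = TRUE, sanitize = FALSE,
                              ...) {
  one <- run_simulation(object, env, init, n_days, guidance = guidance,
                        sanitize = sanitize)
  if (nsim == 1) one else replicate(nsim, one, simplify = FALSE)
}

#' Plot method: training loss trace or simulated trajectories
#'
#' @param x A fitted [attncrop] model.
#' @param which `"trace"` (loss over epochs) or `"simulation"`.
#' @param run A `crop_simulation` (required for `which = "simulation"`).
#' @param factors Factor names to plot (default: leaf and harvest weights).
#' @param truth Optional truth/label data.frame with a `day` column for
#'   overplotting.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.attncrop <- function(x, which = c("trace", "simulation"), run = NULL,
                          factors = c("leaf_dw", "harvest_fw"), truth = NULL,
                          ...) {
  which <- match.arg(which)
  if (which == "trace") {
    tr <- x$trace
    graphics::plot(tr$epoch, tr$total, type = "l", xlab = "epoch",
                   ylab = "mean loss", ...)
    if (!all(is.na(tr$val_total)))
      graphics::lines(tr$epoch, tr$val_total, lty = 2)
    graphics::legend("topright", legend = c("train", "validation"),
                     lty = c(1, 2), bty = "n")
  } else {
    if (is.null(run)) stop("supply a crop_simulation via `run`")
    old <- graphics::par(mfrow = c(1, length(factors)))
    on.exit(graphics::par(old))
    for (f in factors) {
      graphics::plot(run$day, run[[f]], type = "l", xlab = "day", ylab = f,
                     ...)
      if (!is.null(truth) && f %in% names(truth))
        graphics::points(truth$day, truth[[f]], pch = 1, cex = 0.6)
    }
  }
  invisible(x)
}
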