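#' Modeling efficiency (Nash-Sutcliffe form)
#'
#' `EF = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. EF = 1 is a perfect
#' match; EF = 0 means the model performs exactly as well as predicting the
#' observation mean; EF < 0 is worse than the mean.
#'
#' @param y_label Observed values (length >= 2, not all identical).
#' @param y_pred Predicted values, same length.
#' @return EF (<= 1).
#' @export
#' @examples
#' modeling_efficiency(c(0, 1, 2), c(0, 1, 2))  # 1
#' modeling_efficiency(c(0, 1, 2), rep(1, 3))   # 0
modeling_efficiency <- function(y_label, y_pred) {
  if (length(y_label) != length(y_pred)) stop("length mismatch")
  if (length(y_label) < 2L) stop("need at least two observations")
  denom <- sum((y_label - mean(y_label))^2)
  if (denom == 0)
    stop("modeling efficiency is undefined for constant observations")
  1 - sum((y_label - y_pred)^2) / denom
}

#' Normalized root mean squared error
#'
#' RMSE divided by the observed range `max(y) - min(y)`; invariant under
#' positive rescaling of both series.
#'
#' @inheritParams modeling_efficiency
#' @return NRMSE (>= 0).
#' @export
nrmse <- function(y_label, y_pred) {
  if (length(y_label) != length(y_pred)) stop("length mismatch")
  rng <- max(y_label) - min(y_label)
  if (rng == 0) stop("NRMSE is undefined for zero observation range")
  sqrt(mean((y_label - y_pred)^2)) / rng
}

#' Constant mean-of-training baseline
#'
#' The baseline predictor is the per-factor mean of the training-period
#' labels, held constant over the evaluation days. Its EF on the data that
#' define the mean is 0 by construction.
#'
#' @param train_labels Matrix of training-period labels (rows = days,
#'   columns = factors) or a `daily_labels` object.
#' @param eval_days Number of evaluation days (rows to emit).
#' @return Matrix `(eval_days, n_factors)` of constant predictions.
#' @export
mean_baseline <- function(train_labels, eval_days) {
  m <- if (inherits(train_labels, "daily_labels")) train_labels$mean
       else as.matrix(train_labels)
  mu <- colMeans(m)
  matrix(rep(mu, each = eval_days), eval_days, length(mu),
         dimnames = list(NULL, colnames(m)))
}

#' Score a simulation against labels
#'
#' Computes per-factor EF and NRMSE over the days shared by the simulated
#' trajectory and the labels, alongside the same metrics for the constant
#' mean baseline. Factors whose observations are constant over the overlap
#' (metrics undefined) are reported as NA with a warning.
#'
#' @param run A `crop_simulation` from [run_simulation()].
#' @param labels A data.frame with a `day` column and factor columns (e.g. a
#'   reference truth table), or a `daily_labels` object; restrict with
#'   `days` to score at observation days only.
#' @param factors Factor subset to evaluate (default: every factor present
#'   in both).
#' @param days Optional day subset (e.g. destructive sampling days).
#' @param baseline Optional training-period label matrix for the mean
#'   baseline columns.
#' @return data.frame of class `metrics_report` (`factor`, `n`, `ef`,
#'   `nrmse`, `baseline_ef`, `baseline_nrmse`) with attribute `aggregate`:
#'   unweighted means over the evaluated factors.
#' @export
evaluate_simulation <- function(run, labels, factors = NULL, days = NULL,
                                baseline = NULL) {
  if (inherits(labels, "daily_labels")) {
    lab <- as.data.frame(labels$mean)
    lab$day <- labels$day
  } else lab <- as.data.frame(labels)
  if (!"day" %in% names(lab)) stop("labels need a 'day' column")
  common <- intersect(run$day, lab$day)
  if (!is.null(days)) common <- intersect(common, days)
  if (!length(common)) stop("no overlapping days between run and labels")
  if (is.null(factors))
    factors <- setdiff(intersect(names(run), names(lab)), "day")
  rsel <- match(common, run$day)
  lsel <- match(common, lab$day)
  bmu <- if (!is.null(baseline)) colMeans(
    if (inherits(baseline, "daily_labels")) baseline$mean
    else as.matrix(baseline))
  one <- function(f) {
    y <- lab[[f]][lsel]; yh <- run[[f]][rsel]
    ef <- tryCatch(modeling_efficiency(y, yh), error = function(e) NA_real_)
    nr <- tryCatch(nrmse(y, yh), error = function(e) NA_real_)
    bef <- bnr <- NA_real_
    if (!is.null(bmu) && f %in% names(bmu)) {
      yb <- rep(bmu[[f]], length(y))
      bef <- tryCatch(modeling_efficiency(y, yb), error = function(e) NA_real_)
      bnr <- tryCatch(nrmse(y, yb), error = function(e) NA_real_)
    }
    data.frame(factor = f, n = length(y), ef = ef, nrmse = nr,
               baseline_ef = bef, baseline_nrmse = bnr)
  }
  out <- do.call(rbind, lapply(factors, one))
  if (anyNA(out$ef))
    warning("metrics undefined (constant observations) for: ",
            paste(out$factor[is.na(out$ef)], collapse = ", "))
  attr(out, "aggregate") <- c(ef = mean(out$ef, na.rm = TRUE),
                              nrmse = mean(out$nrmse, na.rm = TRUE))
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 3)
  ag <- attr(x, "aggregate")
  cat(sprintf("aggregate: EF %.3f, NRMSE %.3f\n", ag["ef"], ag["nrmse"]))
  invisible(x)
}

#' Extract attention weights from a trained model
#'
#' Runs one window sample through the model in inference mode and returns
#' the decoder self- and cross-attention arrays per requested decoder and
#' block, tagged with a day label (e.g. days after transplanting).
#'
#' @param model A fitted [attncrop] model.
#' @param sample One window sample (list with `features` and `prev`).
#' @param decoders Decoder names (default: all).
#' @param day_tag Optional label stored with the export.
#' @return List of entries `decoder`, `block`, `kind` (self/cross),
#'   `weights` (`(n_heads, query_steps, key_steps)` array, rows summing
#'   to 1), `day_tag`. Convert with [attention_long()].
#' @export
extract_attention <- function(model, sample, decoders = NULL,
                              day_tag = NA) {
  cfg <- model$config
  if (is.null(decoders)) decoders <- names(cfg$decoder_map)
  unknown <- setdiff(decoders, names(cfg$decoder_map))
  if (length(unknown))
    stop("unknown decoder(s): ", paste(unknown, collapse = ", "))
  ba <- stack_batch(list(sample), model$scaler, cfg)
  fw <- model_forward(model$params, cfg, ba$X, ba$P, 1L, model$norm,
                      train = FALSE, capture_attention = TRUE)
  out <- list()
  for (a in fw$attention) {
    if (!a$decoder %in% decoders) next
    w <- a$weights  # (Tq, Tk, H, 1)
    arr <- aperm(array(w[, , , 1L], dim(w)[1:3]), c(3L, 1L, 2L))
    out[[length(out) + 1L]] <- list(decoder = a$decoder, block = a$block,
                                    kind = a$kind, weights = arr,
                                    day_tag = day_tag)
  }
  out
}

#' Flatten attention exports to a long table
#'
#' @param attn Output of [extract_attention()].
#' @return data.frame with columns `decoder`, `block`, `kind`, `head`,
#'   `query`, `key`, `weight`, `day_tag` -- the CSV export schema.
#' @export
attention_long <- function(attn) {
  do.call(rbind, lapply(attn, function(a) {
    d <- dim(a$weights)
    idx <- expand.grid(head = seq_len(d[1]), query = seq_len(d[2]),
                       key = seq_len(d[3]))
    data.frame(decoder = a$decoder, block = a$block, kind = a$kind, idx,
               weight = as.vector(a$weights), day_tag = a$day_tag)
  }))
}

#' Export last-hidden-layer vectors for external embedding
#'
#' Returns the activations of the layer immediately before a decoder's
#' linear head, one row per sample-day, with a lossless metadata key -- the
#' input expected by external 2-D embedding tools (e.g. t-SNE).
#'
#' @param model A fitted [attncrop] model.
#' @param samples List of window samples.
#' @param decoder Which decoder's hidden states to export.
#' @return List with `hidden` (`(n_samples * L, d_model)` matrix) and `meta`
#'   (data.frame: `row`, `sample`, `cultivation`, `day`, `position`,
#'   `decoder`).
#' @export
export_hidden <- function(model, samples, decoder = "leaf") {
  cfg <- model$config
  if (!decoder %in% names(cfg$decoder_map))
    stop("unknown decoder: ", decoder)
  L <- cfg$memory_length
  ba <- stack_batch(samples, model$scaler, cfg)
  fw <- model_forward(model$params, cfg, ba$X, ba$P, ba$B, model$norm,
                      train = FALSE)
  H <- fw$hidden[[decoder]]
  B <- ba$B
  meta <- data.frame(
    row = seq_len(nrow(H)),
    sample = rep(seq_len(B), times = L),
    cultivation = rep(vapply(samples, function(s)
      if (is.null(s$cultivation)) NA_character_ else
        as.character(s$cultivation), ""), times = L),
    day = rep(vapply(samples, function(s)
      if (is.null(s$day)) NA_integer_ else as.integer(s$day), 1L), times = L) +
      rep(seq_len(L), each = B),
    position = rep(seq_len(L), each = B),
    decoder = decoder)
  list(hidden = H, meta = meta)
}

#' Ablation harness
#'
#' Trains and scores model variants along one ablation axis on a shared
#' dataset and seed schedule, so differences in the comparison table are
#' attributable to the variant alone. Variant specifications are validated
#' before any training starts.
#'
#' Supported variant fields by axis: `input`: `drop_features` (character
#' subset of [env_feature_names()], zeroed at the encoder input); `loss`:
#' `loss_mode` (`"multitask"`, `"decoders_only"`, `"single"`); `structure`:
#' `no_gate = TRUE` or `single_decoder = TRUE` (all factors in one decoder);
#' `memory_length`: `memory_length` (integer).
#'
#' @param cultivations Training cultivations (see [make_training_windows()]).
#' @param test List with `env`, `init` and `labels` (truth table or
#'   `daily_labels`) for the held-out scoring cultivation.
#' @param base_config Base [attncrop_config()].
#' @param axis One of `"input"`, `"loss"`, `"structure"`, `"memory_length"`.
#' @param variants Named list of variant specification lists; an empty spec
#'   is the unmodified baseline.
#' @param epochs,batch_size,lr Training settings shared by all variants.
#' @param n_days Days to simulate on the test cultivation.
#' @param factors Factor subset to score.
#' @param seed Shared seed schedule.
#' @return data.frame: one row per variant with aggregate EF and NRMSE.
#' @export
ablation_run <- function(cultivations, test, base_config, axis =
                           c("input", "loss", "structure", "memory_length"),
                         variants, epochs = 10L, batch_size = 32L, lr = 1e-3,
                         n_days = NULL, factors = NULL, seed = 1L) {
  axis <- match.arg(axis)
  allowed <- switch(axis,
    input = "drop_features", loss = "loss_mode",
    structure = c("no_gate", "single_decoder"),
    memory_length = "memory_length")
  cfgs <- list()
  for (nm in names(variants)) {
    sp <- variants[[nm]]
    bad <- setdiff(names(sp), allowed)
    if (length(bad))
      stop("variant '", nm, "': field(s) ", paste(bad, collapse = ", "),
           " not valid for axis '", axis, "'")
    cfg <- base_config
    if (!is.null(sp$drop_features)) {
      unknown <- setdiff(sp$drop_features, env_feature_names())
      if (length(unknown))
        stop("variant '", nm, "': unknown feature(s) ",
             paste(unknown, collapse = ", "))
      cfg$feature_mask <- !(env_feature_names() %in% sp$drop_features)
    }
    if (!is.null(sp$loss_mode)) {
      if (!sp$loss_mode %in% c("multitask", "decoders_only", "single"))
        stop("variant '", nm, "': invalid loss_mode '", sp$loss_mode, "'")
      cfg$loss_mode <- sp$loss_mode
    }
    if (isTRUE(sp$no_gate)) cfg$use_gate <- FALSE
    if (isTRUE(sp$single_decoder)) {
      cfg$decoder_map <- list(all = seq_along(cfg$factor_names))
      if (cfg$loss_mode == "multitask") cfg$loss_mode <- "single"
    }
    if (!is.null(sp$memory_length))
      cfg$memory_length <- as.integer(sp$memory_length)
    check_decoder_map(cfg$decoder_map, length(cfg$factor_names))
    cfgs[[nm]] <- cfg
  }
  rows <- list()
  for (nm in names(cfgs)) {
    cfg <- cfgs[[nm]]
    w <- make_training_windows(cultivations, cfg$memory_length, seed = seed)
    fit <- attncrop(w, cfg, epochs = epochs, batch_size = batch_size,
                    lr = lr, seed = seed)
    nd <- if (is.null(n_days)) {
      daily <- compute_daily_features(test$env)
      max(daily$day) - cfg$memory_length
    } else n_days
    run <- run_simulation(fit, test$env, test$init, nd)
    rep <- suppressWarnings(
      evaluate_simulation(run, test$labels, factors = factors))
    ag <- attr(rep, "aggregate")
    rows[[nm]] <- data.frame(variant = nm, axis = axis, ef = ag[["ef"]],
                             nrmse = ag[["nrmse"]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
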