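ns <- asNamespace("attncrop")

test_that("scaler standardizes training data and round-trips exactly", {
  w <- tiny_windows()
  scaler <- suppressWarnings(fit_scaler(w$train))
  feats <- do.call(rbind, lapply(w$train, `[[`, "features"))
  z <- scale_transform(feats, scaler, "features")
  expect_equal(unname(colMeans(z)), rep(0, 7), tolerance = 1e-10)
  nonconst <- apply(feats, 2, stats::sd) > 0
  expect_equal(unname(apply(z[, nonconst], 2, stats::sd)),
               rep(1, sum(nonconst)), tolerance = 1e-10)
  back <- scale_invert(z, scaler, "features")
  expect_equal(back, feats, tolerance = 1e-9)
  # a zero-variance factor column gets scale 1 with a warning
  s0 <- w$train[1:2]
  for (i in 1:2) s0[[i]]$prev[, "stem_count"] <- 2
  for (i in 1:2) s0[[i]]$target[, "stem_count"] <- 2
  expect_warning(sc0 <- fit_scaler(s0), "zero-variance")
  expect_equal(unname(sc0$fac_sd[["stem_count"]]), 1)
})

test_that("validation data are transformed with training statistics", {
  w <- tiny_windows()
  scaler <- suppressWarnings(fit_scaler(w$train))
  shifted <- matrix(1000, 4, 7, dimnames = list(NULL, env_feature_names()))
  z <- scale_transform(shifted, scaler, "features")
  # a shifted set is NOT centered under the training scaler
  expect_true(all(abs(colMeans(z)) > 1))
})

test_that("loss assembly: zero for perfect predictions, eight terms, oracle", {
  cfg <- micro_config(L = 1L)
  nf <- length(cfg$factor_names)
  target <- matrix(rnorm(nf), 1, nf, dimnames = list(NULL, cfg$factor_names))
  perfect <- lapply(cfg$decoder_map, function(idx)
    target[, idx, drop = FALSE])
  lb <- assemble_loss(perfect, target, cfg)
  expect_s3_class(lb, "loss_breakdown")
  expect_length(lb$terms, 8L)
  expect_equal(unname(lb$terms), rep(0, 8))
  expect_equal(lb$total, 0)
  # hand-computed oracle on a one-day toy: only leaf_fw off by e
  e <- 0.7
  preds <- perfect
  col <- match(match("leaf_fw", cfg$factor_names), cfg$decoder_map$leaf)
  preds$leaf[, col] <- preds$leaf[, col] + e
  lb2 <- assemble_loss(preds, target, cfg)
  # leaf decoder MSE = e^2 / 4 (four leaf factors, one day);
  # veg FW sum off by e -> veg_fw = e^2; DW untouched
  expect_equal(unname(lb2$terms[["leaf"]]), e^2 / 4)
  expect_equal(unname(lb2$terms[["veg_fw"]]), e^2)
  expect_equal(unname(lb2$terms[["veg_dw"]]), 0)
  expect_equal(lb2$total, (e^2 / 4 + e^2) / 8)
  expect_equal(lb2$total, mean(lb2$terms))
})

test_that("conservation terms vanish for compensating organ errors", {
  cfg <- micro_config(L = 1L)
  nf <- length(cfg$factor_names)
  target <- matrix(0, 1, nf, dimnames = list(NULL, cfg$factor_names))
  preds <- lapply(cfg$decoder_map, function(idx)
    matrix(0, 1, length(idx)))
  # leaf_fw +1 and stem_fw -1: individually wrong, sum conserved
  lcol <- match(match("leaf_fw", cfg$factor_names), cfg$decoder_map$leaf)
  scol <- match(match("stem_fw", cfg$factor_names), cfg$decoder_map$stem)
  preds$leaf[, lcol] <- 1
  preds$stem[, scol] <- -1
  lb <- assemble_loss(preds, target, cfg)
  expect_equal(unname(lb$terms[["veg_fw"]]), 0)
  expect_gt(lb$terms[["leaf"]], 0)
})

test_that("loss total is invariant to decoder evaluation order", {
  cfg <- micro_config(L = 2L)
  ba <- random_batch(cfg, B = 2L)
  p <- ns$init_params(cfg)
  fw <- ns$model_forward(p, cfg, ba$X, ba$P, ba$B, ns$init_norm_state(cfg))
  lb <- assemble_loss(fw$preds, ba$target, cfg)
  lb_rev <- assemble_loss(rev(fw$preds), ba$target, cfg)
  expect_equal(lb_rev$total, lb$total)
})

test_that("loss modes: single pooled term and decoders-only", {
  cfg1 <- micro_config(L = 1L, loss_mode = "single")
  cfg6 <- micro_config(L = 1L, loss_mode = "decoders_only")
  nf <- length(cfg1$factor_names)
  target <- matrix(rnorm(nf), 1, nf, dimnames = list(NULL, cfg1$factor_names))
  preds <- lapply(cfg1$decoder_map, function(idx)
    target[, idx, drop = FALSE] + 1)
  expect_length(assemble_loss(preds, target, cfg1)$terms, 1L)
  expect_length(assemble_loss(preds, target, cfg6)$terms, 6L)
})

test_that("training descends, is seeded, and tracks the best state", {
  w <- tiny_windows()
  cfg <- micro_config()
  fit1 <- suppressWarnings(train_attncrop(w, cfg, epochs = 4L, seed = 3L))
  expect_lt(fit1$trace$total[4], fit1$trace$total[1])
  fit2 <- suppressWarnings(train_attncrop(w, cfg, epochs = 4L, seed = 3L))
  expect_identical(fit1$trace$total[1], fit2$trace$total[1])
  expect_identical(fit1$params, fit2$params)
  # best-state selection: returned state's val loss is the trace minimum
  expect_equal(fit1$trace$val_total[fit1$best_epoch],
               min(fit1$trace$val_total))
  # trace has the eight loss columns plus bookkeeping
  expect_true(all(c("epoch", "status", "leaf", "veg_fw", "veg_dw", "total",
                    "val_total") %in% names(fit1$trace)))
})

test_that("checkpoints round-trip forward outputs exactly", {
  fit <- tiny_fit()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  ba <- random_batch(fit$config, B = 2L)
  f1 <- ns$model_forward(fit$params, fit$config, ba$X, ba$P, ba$B, fit$norm)
  f2 <- ns$model_forward(back$params, back$config, ba$X, ba$P, ba$B,
                         back$norm)
  expect_identical(f1$preds, f2$preds)
  expect_s3_class(back, "attncrop")
})

test_that("checkpoint guards: missing file, scaler, decoder-map mismatch", {
  expect_error(load_checkpoint("/nonexistent/ckpt.rds"), "not found")
  fit <- tiny_fit()
  path <- withr::local_tempfile(fileext = ".rds")
  # strip the scaler
  obj <- list(format = "attncrop-checkpoint", version = 1L,
              config = fit$config, params = fit$params,
              norm = as.list(fit$norm), scaler = NULL)
  saveRDS(obj, path)
  expect_error(load_checkpoint(path), "scaler")
  # swap the config for a mismatched decoder map
  cfg2 <- fit$config
  cfg2$decoder_map <- list(all = seq_along(cfg2$factor_names))
  obj$scaler <- fit$scaler
  obj$config <- cfg2
  saveRDS(obj, path)
  expect_error(load_checkpoint(path), "mismatch")
})
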