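test_that("modeling efficiency anchors: perfect fit and mean predictor", {
  y <- c(1, 2, 3, 4)
  expect_equal(modeling_efficiency(y, y), 1)
  expect_equal(modeling_efficiency(y, rep(mean(y), 4)), 0)
  # hand evaluation: y = [0,1,2], pred = 0 -> 1 - 5/2
  expect_equal(modeling_efficiency(c(0, 1, 2), c(0, 0, 0)), -1.5)
  expect_error(modeling_efficiency(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(modeling_efficiency(1:3, 1:4), "length")
})

test_that("NRMSE anchors and scale invariance", {
  expect_equal(nrmse(c(0, 2), c(0, 2)), 0)
  expect_equal(nrmse(c(0, 2), c(1, 1)), 0.5)  # RMSE 1 over range 2
  y <- c(1, 3, 7); p <- c(2, 2, 5)
  expect_equal(nrmse(3 * y, 3 * p), nrmse(y, p))
  expect_error(nrmse(c(1, 1), c(1, 2)), "zero")
})

test_that("metrics match brute-force formula evaluation on random vectors", {
  set.seed(123)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    y <- rnorm(n, sd = runif(1, 0.5, 3))
    p <- y + rnorm(n, sd = runif(1, 0.1, 2))
    ef_oracle <- 1 - sum((y - p)^2) / sum((y - mean(y))^2)
    nr_oracle <- sqrt(sum((y - p)^2) / n) / (max(y) - min(y))
    expect_equal(modeling_efficiency(y, p), ef_oracle, tolerance = 1e-10)
    expect_equal(nrmse(y, p), nr_oracle, tolerance = 1e-10)
  }
})

test_that("EF shift invariance and NRMSE scaling invariance hold", {
  set.seed(7)
  y <- rnorm(20); p <- y + rnorm(20, sd = 0.3)
  expect_equal(modeling_efficiency(y + 5, p + 5), modeling_efficiency(y, p))
  expect_equal(nrmse(2.5 * y, 2.5 * p), nrmse(y, p))
  expect_lte(modeling_efficiency(y, p), 1)
})

test_that("mean baseline is constant and scores EF 0 on its own data", {
  m <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  base <- mean_baseline(m, eval_days = 3)
  expect_equal(dim(base), c(3L, 2L))
  expect_equal(unique(base[, "a"]), 2)
  expect_equal(modeling_efficiency(m[, "a"], base[, "a"]), 0)
  # 3-point toy: baseline NRMSE = sqrt(mean sq dev) / range
  expect_equal(nrmse(m[, "a"], base[, "a"]), sqrt(2 / 3) / 2)
})

test_that("evaluating truth against itself gives EF 1, NRMSE 0", {
  truth <- tiny_truth()
  run <- truth[truth$day >= 4, c("day", crop_factors()$name)]
  class(run) <- c("crop_simulation", "data.frame")
  rep <- suppressWarnings(evaluate_simulation(run, truth))
  ok <- !is.na(rep$ef)
  expect_true(any(ok))
  expect_equal(rep$ef[ok], rep(1, sum(ok)))
  expect_equal(rep$nrmse[ok], rep(0, sum(ok)))
  # constant factors (stem count) are NA with a warning
  expect_warning(evaluate_simulation(run, truth), "constant")
})

test_that("day restriction and aggregate follow the report contract", {
  truth <- tiny_truth()
  run <- truth[truth$day >= 4, c("day", crop_factors()$name)]
  run$leaf_dw <- run$leaf_dw * 1.1
  class(run) <- c("crop_simulation", "data.frame")
  full <- evaluate_simulation(run, truth, factors = c("leaf_dw", "leaf_fw"))
  expect_equal(unique(full$n), nrow(run))
  sub <- evaluate_simulation(run, truth, factors = c("leaf_dw", "leaf_fw"),
                             days = c(10L, 20L, 30L))
  expect_equal(unique(sub$n), 3L)
  # aggregate = unweighted mean over the evaluated factors (2-factor toy)
  expect_equal(unname(attr(full, "aggregate")["ef"]), mean(full$ef))
  expect_error(evaluate_simulation(run, truth, days = 1000L), "overlap")
})

test_that("baseline columns appear when training labels are supplied", {
  truth <- tiny_truth()
  run <- truth[truth$day >= 4, c("day", crop_factors()$name)]
  class(run) <- c("crop_simulation", "data.frame")
  rep <- evaluate_simulation(run, truth, factors = c("leaf_dw", "harvest_fw"),
                             baseline = as.matrix(truth[, crop_factors()$name]))
  expect_true(all(is.finite(rep$baseline_ef)))
  # the simulated (= true) series beats the constant baseline
  expect_true(all(rep$ef > rep$baseline_ef))
})

test_that("attention export: shapes, normalization, causality, day tags", {
  fit <- tiny_fit()
  w <- tiny_windows()
  attn <- extract_attention(fit, w$train[[1]], day_tag = 20)
  expect_gt(length(attn), 0)
  cfg <- fit$config
  L <- cfg$memory_length
  for (a in attn) {
    if (a$kind == "cross")
      expect_equal(dim(a$weights), c(cfg$n_heads, L, 24L * L))
    else expect_equal(dim(a$weights), c(cfg$n_heads, L, L))
    sums <- apply(a$weights, c(1, 2), sum)
    expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-5)
    if (a$kind == "self")
      for (i in seq_len(L - 1))
        expect_true(all(a$weights[, i, (i + 1):L] == 0))
    expect_equal(a$day_tag, 20)
  }
  long <- attention_long(attn)
  expect_setequal(names(long), c("decoder", "block", "kind", "head", "query",
                                 "key", "weight", "day_tag"))
  expect_error(extract_attention(fit, w$train[[1]], decoders = "roots"),
               "unknown")
})

test_that("hidden-layer export is keyed, deterministic and complete", {
  fit <- tiny_fit()
  w <- tiny_windows()
  samples <- w$train[1:3]
  h1 <- export_hidden(fit, samples, decoder = "leaf")
  expect_equal(nrow(h1$hidden), 3L * fit$config$memory_length)
  expect_equal(nrow(h1$meta), nrow(h1$hidden))
  expect_equal(h1$meta$row, seq_len(nrow(h1$hidden)))
  h2 <- export_hidden(fit, samples, decoder = "leaf")
  expect_identical(h1$hidden, h2$hidden)
  # identical samples produce identical rows
  h3 <- export_hidden(fit, list(samples[[1]], samples[[1]]), decoder = "leaf")
  expect_equal(h3$hidden[1, ], h3$hidden[2, ])
  expect_error(export_hidden(fit, samples, decoder = "roots"), "unknown")
})

test_that("ablation specs are validated before any training", {
  cfg <- micro_config()
  cult <- list(list(env = tiny_env(), labels = tiny_labels(), id = "a"))
  test <- list(env = tiny_env(), init = NULL, labels = tiny_truth())
  expect_error(
    ablation_run(cult, test, cfg, axis = "input",
                 variants = list(v = list(loss_mode = "single"))),
    "not valid for axis")
  expect_error(
    ablation_run(cult, test, cfg, axis = "input",
                 variants = list(v = list(drop_features = "moonlight"))),
    "unknown feature")
  expect_error(
    ablation_run(cult, test, cfg, axis = "loss",
                 variants = list(v = list(loss_mode = "nonsense"))),
    "invalid loss_mode")
})

test_that("single-decoder ablation collapses the loss to one term", {
  cfg <- micro_config()
  cfg$decoder_map <- list(all = seq_along(cfg$factor_names))
  cfg$loss_mode <- "single"
  nf <- length(cfg$factor_names)
  target <- matrix(rnorm(nf), 1, nf, dimnames = list(NULL, cfg$factor_names))
  preds <- list(all = target + 1)
  lb <- assemble_loss(preds, target, cfg)
  expect_length(lb$terms, 1L)
  expect_equal(unname(lb$terms), 1)
})

test_that("ablation harness runs variants on a shared held-out scenario", {
  cult <- list(list(env = tiny_env(), labels = tiny_labels(), id = "a"))
  init <- stats::setNames(as.numeric(tiny_truth()[1, crop_factors()$name]),
                          crop_factors()$name)
  test <- list(env = tiny_env(), init = init, labels = tiny_truth())
  tab <- suppressWarnings(ablation_run(
    cult, test, micro_config(), axis = "memory_length",
    variants = list(L3 = list(memory_length = 3L),
                    L4 = list(memory_length = 4L)),
    epochs = 1L, n_days = 8L,
    factors = c("leaf_dw", "harvest_fw"), seed = 2L))
  expect_equal(tab$variant, c("L3", "L4"))
  expect_true(all(is.finite(tab$ef)))
})
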