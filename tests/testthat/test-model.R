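ns <- asNamespace("attncrop")

test_that("configuration guards reject inconsistent architectures", {
  expect_error(attncrop_config(d_model = 30, n_heads = 4), "divisible")
  expect_error(attncrop_config(d_model = 30, n_heads = 2,
                               kernels = c(1, 3, 5, 7)), "branches")
  bad_map <- default_decoder_map()
  bad_map$leaf <- bad_map$leaf[-1]
  expect_error(attncrop_config(decoder_map = bad_map), "cover")
  dup_map <- default_decoder_map()
  dup_map$status <- c(dup_map$status, dup_map$leaf[1])
  expect_error(attncrop_config(decoder_map = dup_map), "disjoint")
  expect_error(ns$check_decoder_map(list(), 21), "at least one")
})

test_that("forward pass respects all shape contracts", {
  for (L in c(1L, 3L)) {
    cfg <- micro_config(L = L)
    p <- ns$init_params(cfg)
    ba <- random_batch(cfg, B = 2L)
    fw <- ns$model_forward(p, cfg, ba$X, ba$P, ba$B, ns$init_norm_state(cfg))
    expect_named(fw$preds, names(default_decoder_map()))
    expect_length(fw$preds, 6L)
    # encoder input rows = 24 x decoder output rows
    expect_equal(nrow(ba$X), 24L * nrow(fw$preds$status))
    expect_equal(dim(fw$preds$status), c(2L * L, 2L))    # status: 2 factors
    expect_equal(dim(fw$preds$property), c(2L * L, 2L))
    expect_equal(dim(fw$preds$stem), c(2L * L, 5L))
    expect_equal(dim(fw$hidden$leaf), c(2L * L, cfg$d_model))
  }
  cfg <- micro_config(L = 2L)
  p <- ns$init_params(cfg)
  ba <- random_batch(cfg, B = 2L)
  expect_error(ns$model_forward(p, cfg, ba$X[-1, ], ba$P, 2L,
                                ns$init_norm_state(cfg)), "24")
})

test_that("six decoders share structure: identical parameter counts", {
  cfg <- micro_config()
  p <- ns$init_params(cfg)
  body_count <- function(nm) {
    # decoder parameters excluding the factor-specific head
    all <- ns$count_params(p, paste0("dec_", nm))
    head <- ns$count_params(p, paste0("dec_", nm, "_head"))
    all - head
  }
  counts <- vapply(names(cfg$decoder_map), body_count, 1)
  expect_equal(length(unique(counts)), 1L)
})

test_that("embedding branch widths sum to d_model", {
  cfg <- micro_config()
  p <- ns$init_params(cfg)
  widths <- vapply(seq_along(cfg$kernels), function(i)
    ncol(p[[paste0("enc_emb_k", i, "_W")]]), 1L)
  expect_equal(sum(widths), cfg$d_model)
})

test_that("inference is deterministic and position-sensitive", {
  cfg <- micro_config()
  p <- ns$init_params(cfg)
  ba <- random_batch(cfg, B = 2L)
  st <- ns$init_norm_state(cfg)
  f1 <- ns$model_forward(p, cfg, ba$X, ba$P, ba$B, st)
  f2 <- ns$model_forward(p, cfg, ba$X, ba$P, ba$B, st)
  expect_identical(f1$preds, f2$preds)
  # permuting two input hours changes the output (positional encoding)
  Xp <- ba$X
  Xp[c(1, 1 + 2 * ba$B), ] <- Xp[c(1 + 2 * ba$B, 1), ]
  f3 <- ns$model_forward(p, cfg, Xp, ba$P, ba$B, st)
  expect_false(isTRUE(all.equal(f1$preds$leaf, f3$preds$leaf)))
})

test_that("look-ahead causality holds through the full model", {
  cfg <- micro_config(L = 4L)
  p <- ns$init_params(cfg)
  ba <- random_batch(cfg, B = 2L)
  st <- ns$init_norm_state(cfg)
  base <- ns$model_forward(p, cfg, ba$X, ba$P, ba$B, st)
  B <- ba$B
  for (i in 2:4) {
    P2 <- ba$P
    P2[1 + (i - 1) * B, ] <- P2[1 + (i - 1) * B, ] + 7   # sample 1, day i
    pert <- ns$model_forward(p, cfg, ba$X, P2, B, st)
    for (nm in names(base$preds)) {
      for (j in seq_len(i - 1)) {
        expect_identical(base$preds[[nm]][1 + (j - 1) * B, ],
                         pert$preds[[nm]][1 + (j - 1) * B, ])
      }
      # and the perturbed day itself must change somewhere
    }
    expect_false(isTRUE(all.equal(base$preds$leaf[1 + (i - 1) * B, ],
                                  pert$preds$leaf[1 + (i - 1) * B, ])))
  }
})

test_that("attention rows sum to 1 and masked entries are exactly zero", {
  cfg <- micro_config(L = 3L)
  p <- ns$init_params(cfg)
  ba <- random_batch(cfg, B = 2L)
  fw <- ns$model_forward(p, cfg, ba$X, ba$P, ba$B, ns$init_norm_state(cfg),
                         capture_attention = TRUE)
  expect_gt(length(fw$attention), 0)
  for (a in fw$attention) {
    w <- a$weights   # (Tq, Tk, H, B)
    sums <- apply(w, c(1, 3, 4), sum)
    expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-5)
    if (a$kind == "self") {
      L <- dim(w)[1]
      for (i in seq_len(L - 1))
        expect_identical(as.vector(w[i, (i + 1):L, , ]),
                         rep(0, (L - i) * dim(w)[3] * dim(w)[4]))
    }
  }
})

test_that("input gate blends encoded memory with projected raw input", {
  cfg <- micro_config(L = 2L)
  p <- ns$init_params(cfg)
  ba <- random_batch(cfg, B = 2L)
  st <- ns$init_norm_state(cfg)
  # force g = 1: huge positive gate bias -> memory equals encoder output
  p1 <- p; p1$gate_W[] <- 0; p1$gate_b[] <- 1e4
  f1 <- ns$model_forward(p1, cfg, ba$X, ba$P, ba$B, st)
  enc_out <- f1$cache$gate$enc_out
  expect_equal(f1$cache$mem, enc_out, tolerance = 1e-12)
  # force g = 0 -> memory equals the projected raw features
  p0 <- p; p0$gate_W[] <- 0; p0$gate_b[] <- -1e4
  f0 <- ns$model_forward(p0, cfg, ba$X, ba$P, ba$B, st)
  expect_equal(f0$cache$mem, f0$cache$gate$proj$out, tolerance = 1e-12)
  # generic gate stays strictly inside (0, 1)
  f <- ns$model_forward(p, cfg, ba$X, ba$P, ba$B, st)
  expect_true(all(f$cache$gate$g > 0 & f$cache$gate$g < 1))
})

test_that("decoders do not interfere given the same memory", {
  cfg <- micro_config(L = 2L)
  p <- ns$init_params(cfg)
  ba <- random_batch(cfg, B = 2L)
  st <- ns$init_norm_state(cfg)
  base <- ns$model_forward(p, cfg, ba$X, ba$P, ba$B, st)
  # ruining one decoder's parameters leaves all other outputs unchanged
  p2 <- p
  for (nm in names(p2)[startsWith(names(p2), "dec_harvest")])
    p2[[nm]] <- p2[[nm]] * 0
  f2 <- ns$model_forward(p2, cfg, ba$X, ba$P, ba$B, st)
  for (nm in setdiff(names(base$preds), "harvest"))
    expect_identical(base$preds[[nm]], f2$preds[[nm]])
  expect_false(isTRUE(all.equal(base$preds$harvest, f2$preds$harvest)))
})
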