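test_that("observation container enforces physical invariants", {
  m <- matrix(c(8, 16), 2, 1, dimnames = list(NULL, "leaf_fw"))
  s <- matrix(c(1, 2), 2, 1)
  expect_s3_class(growth_obs(c(10L, 20L), m, s, c(4L, 4L)), "growth_obs")
  expect_error(growth_obs(c(20L, 10L), m, s, c(4L, 4L)), "increasing")
  expect_error(growth_obs(c(10L, 20L), -m, s, c(4L, 4L)), "non-negative")
  mm <- cbind(leaf_fw = c(1, 2), leaf_dw = c(2, 3))
  expect_error(growth_obs(c(1L, 2L), mm, mm * 0, c(4L, 4L)), "fresh weight")
})

test_that("daily interpolation anchors day 0 at half the first observation", {
  obs <- growth_obs(c(10L, 20L),
                    matrix(c(8, 16), 2, 1, dimnames = list(NULL, "leaf_fw")),
                    matrix(c(1, 2), 2, 1), c(4L, 4L))
  lab <- interpolate_growth_daily(obs)
  expect_equal(lab$day, 0:20)
  expect_equal(lab$mean[lab$day == 0, ], c(leaf_fw = 4))    # 50% anchor
  expect_equal(lab$sd[lab$day == 0, ], 0.5)
  # midpoint: observations 10 (day 10) and 20 (day 20) -> 15 at day 15
  obs2 <- growth_obs(c(10L, 20L),
                     matrix(c(10, 20), 2, 1,
                            dimnames = list(NULL, "leaf_fw")),
                     matrix(0, 2, 1), c(4L, 4L))
  lab2 <- interpolate_growth_daily(obs2)
  expect_equal(unname(lab2$mean[lab2$day == 15, ]), 15)
  # nodes reproduced exactly
  expect_equal(unname(lab$mean[lab$day %in% c(10, 20), ]), c(8, 16))
  # alternative start rule
  lab25 <- interpolate_growth_daily(obs, start_rule = 0.25)
  expect_equal(unname(lab25$mean[1, ]), 2)
})

test_that("interpolated series hits every observation exactly", {
  lab <- tiny_labels()
  obs <- sample_destructive_observations(tiny_truth(), n_dates = 4L,
                                         cv = 0.05, seed = 11L)
  sel <- match(obs$day, lab$day)
  expect_equal(unname(lab$mean[sel, ]), unname(obs$mean))
  expect_equal(unname(lab$sd[sel, ]), unname(obs$sd))
})

test_that("augmentation is degenerate at SD = 0 and seeded", {
  lab <- tiny_labels()
  lab0 <- lab
  lab0$sd[] <- 0
  draws <- augment_labels(lab0, n_draws = 3L, seed = 9L)
  for (d in draws) expect_equal(d, lab0$mean)
  a <- augment_labels(lab, n_draws = 2L, seed = 4L)
  b <- augment_labels(lab, n_draws = 2L, seed = 4L)
  expect_identical(a, b)
  c2 <- augment_labels(lab, n_draws = 2L, seed = 5L)
  expect_false(identical(a, c2))
  expect_error(augment_labels(lab, n_draws = 0L), "n_draws")
})

test_that("augmentation preserves the per-day expectation (CLT bound)", {
  # one factor, mean 10, sd 2, many draws
  lab <- structure(list(day = 0:1,
                        mean = matrix(10, 2, 1,
                                      dimnames = list(NULL, "leaf_fw")),
                        sd = matrix(2, 2, 1)), class = "daily_labels")
  draws <- augment_labels(lab, n_draws = 10000L, seed = 2L)
  xs <- vapply(draws, function(d) d[1, 1], 1)
  se <- 2 / sqrt(10000)
  expect_lt(abs(mean(xs) - 10), 3 * se)
})

test_that("augmented cumulative-harvest trajectories are non-decreasing", {
  lab <- tiny_labels()
  draws <- augment_labels(lab, n_draws = 5L, seed = 13L)
  cumcols <- crop_factors()$name[crop_factors()$cumulative]
  for (d in draws) {
    for (col in cumcols) expect_true(all(diff(d[, col]) >= 0))
    expect_true(all(d >= 0))
  }
})

test_that("window enumeration matches an independent day-index oracle", {
  env <- tiny_env()
  lab <- tiny_labels()
  L <- 3L
  w <- make_training_windows(list(list(env = env, labels = lab)), L,
                             split = 1)
  # oracle: prev days d..d+L-1 and target d+1..d+L must be labeled days,
  # and the environment must cover day d+L
  n_env <- max(compute_daily_features(env)$day)
  count <- 0L
  for (d in min(lab$day):max(lab$day)) {
    if (d + L <= max(lab$day) && d + L <= n_env) count <- count + 1L
  }
  expect_equal(length(w$train), count)
  s <- w$train[[1]]
  expect_equal(dim(s$features), c(24L * L, 7L))
  expect_equal(dim(s$prev), c(L, ncol(lab$mean)))
  expect_equal(dim(s$target), c(L, ncol(lab$mean)))
  # target is prev shifted by one day
  d0 <- s$day
  expect_equal(s$prev, lab$mean[match(d0:(d0 + L - 1), lab$day), ])
  expect_equal(s$target, lab$mean[match((d0 + 1):(d0 + L), lab$day), ])
})

test_that("sample split is a disjoint complete partition, seed-dependent", {
  env <- tiny_env()
  lab <- tiny_labels()
  w <- make_training_windows(list(list(env = env, labels = lab)), 3L,
                             split = 0.7, seed = 1L)
  n <- length(w$train) + length(w$val)
  expect_equal(length(w$train), round(0.7 * n))
  key <- function(s) paste(s$cultivation, s$draw, s$day)
  expect_length(intersect(sapply(w$train, key), sapply(w$val, key)), 0L)
  w2 <- make_training_windows(list(list(env = env, labels = lab)), 3L,
                              split = 0.7, seed = 2L)
  expect_false(identical(sapply(w$train, key), sapply(w2$train, key)))
})

test_that("windows never mix cultivations and short cultivations error", {
  env <- tiny_env()
  lab <- tiny_labels()
  w <- make_training_windows(list(list(env = env, labels = lab, id = "a"),
                                  list(env = env, labels = lab, id = "b")),
                             3L, split = 1)
  expect_setequal(unique(sapply(w$train, `[[`, "cultivation")), c("a", "b"))
  short <- lab
  keep <- lab$day <= 2
  short$day <- lab$day[keep]
  short$mean <- lab$mean[keep, , drop = FALSE]
  short$sd <- lab$sd[keep, , drop = FALSE]
  expect_error(
    make_training_windows(list(list(env = env, labels = short)), 7L),
    "too short")
})

test_that("growth CSV round trip is lossless", {
  obs <- sample_destructive_observations(tiny_truth(), n_dates = 3L,
                                         seed = 21L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_growth_csv(obs, path)
  back <- read_growth_csv(path)
  expect_equal(back$day, obs$day)
  expect_equal(back$mean, obs$mean, tolerance = 1e-9)
  expect_equal(back$sd, obs$sd, tolerance = 1e-9)
  expect_equal(back$n_plants, obs$n_plants)
})
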