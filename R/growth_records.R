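# run code with a temporarily fixed RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(code)
}

#' Destructive-sampling growth observations
#'
#' Container for sparse growth measurements from periodic destructive
#' investigations: per sampling day, the per-plant mean and standard deviation
#' of every growth factor, and the number of plants measured.
#'
#' @param day Integer day indices from cultivation start (day 1 = first day
#'   with environment data), strictly increasing.
#' @param mean Matrix `(n_obs, n_factors)` of per-plant factor means; columns
#'   named as in [crop_factors()].
#' @param sd Matrix of matching standard deviations.
#' @param n_plants Integer count of plants per investigation.
#' @return Object of class `growth_obs`.
#' @export
growth_obs <- function(day, mean, sd, n_plants) {
  mean <- as.matrix(mean); sd <- as.matrix(sd)
  rownames(mean) <- NULL; rownames(sd) <- NULL
  if (is.unsorted(day, strictly = TRUE))
    stop("observation days must be strictly increasing")
  stopifnot(nrow(mean) == length(day), all(dim(mean) == dim(sd)),
            length(n_plants) == length(day))
  if (any(mean < 0)) stop("factor means must be non-negative")
  if (any(sd < 0)) stop("factor standard deviations must be non-negative")
  fac <- colnames(mean)
  if (!is.null(fac)) {
    for (org in c("leaf", "stem", "petiole", "harvest")) {
      fw <- paste0(org, "_fw"); dw <- paste0(org, "_dw")
      if (all(c(fw, dw) %in% fac) && any(mean[, fw] < mean[, dw]))
        stop("fresh weight must be >= dry weight for organ '", org, "'")
    }
  }
  structure(list(day = as.integer(day), mean = mean, sd = sd,
                 n_plants = as.integer(n_plants)),
            class = "growth_obs")
}

#' Interpolate sparse observations to daily training labels
#'
#' A virtual day-0 anchor is prepended with every factor (mean and SD) set to
#' `start_rule` (default 50 percent) of the first observation -- the crop at
#' transplanting is taken as half its first measured size. Means and SDs are
#' then linearly interpolated to every day between the anchor and the last
#' observation; values at observation days equal the observations exactly.
#'
#' @param obs A [growth_obs()].
#' @param start_rule Fraction of the first observation used for the day-0
#'   anchor (default 0.5).
#' @return Object of class `daily_labels`: list with `day` (0-based integer
#'   vector), `mean` and `sd` matrices `(n_days, n_factors)`.
#' @export
#' @examples
#' obs <- growth_obs(day = c(10L, 20L),
#'                   mean = matrix(c(8, 16), 2, 1, dimnames = list(NULL, "leaf_fw")),
#'                   sd = matrix(c(1, 2), 2, 1), n_plants = c(4L, 4L))
#' lab <- interpolate_growth_daily(obs)
#' lab$mean[lab$day == 0, ]   # 4: half of the first observation
#' lab$mean[lab$day == 15, ]  # 12: midpoint
interpolate_growth_daily <- function(obs, start_rule = 0.5) {
  stopifnot(inherits(obs, "growth_obs"), start_rule >= 0)
  day <- obs$day; mu <- obs$mean; sdm <- obs$sd
  if (day[1] > 0L) {
    day <- c(0L, day)
    mu <- rbind(start_rule * mu[1, ], mu)
    sdm <- rbind(start_rule * sdm[1, ], sdm)
  }
  if (length(day) < 2L)
    stop("need at least two support points (observations plus anchor)")
  days <- day[1]:day[length(day)]
  interp <- function(m) {
    out <- apply(m, 2, function(y) stats::approx(day, y, xout = days)$y)
    if (any(out < 0)) {
      warning("negative interpolants clipped to 0")
      out[out < 0] <- 0
    }
    out
  }
  structure(list(day = days, mean = interp(mu), sd = interp(sdm)),
            class = "daily_labels")
}

#' Stochastic augmentation of daily labels
#'
#' For each draw and day, per-factor labels are sampled from
#' `Normal(mean, SD)` truncated at 0; cumulative factors (status and harvest
#' groups) are re-monotonized by a running maximum so every augmented
#' trajectory remains non-decreasing where the quantity is cumulative by
#' definition. The seed fixes the draws exactly.
#'
#' @param daily A `daily_labels` object.
#' @param n_draws Number of augmented label sets (>= 1).
#' @param seed Integer seed.
#' @param cumulative Logical vector (length n_factors) flagging cumulative
#'   factors; defaults to the flags of [crop_factors()] matched by column
#'   name, or all-FALSE when columns are unnamed.
#' @return List of `n_draws` matrices `(n_days, n_factors)`.
#' @export
augment_labels <- function(daily, n_draws, seed = 1L, cumulative = NULL) {
  stopifnot(inherits(daily, "daily_labels"))
  if (n_draws < 1L) stop("n_draws must be >= 1")
  if (anyNA(daily$sd) || any(!is.finite(daily$sd)))
    stop("label SDs must be finite")
  mu <- daily$mean; sdm <- daily$sd
  n <- nrow(mu); p <- ncol(mu)
  if (is.null(cumulative)) {
    fac <- crop_factors()
    cn <- colnames(mu)
    cumulative <- if (is.null(cn)) rep(FALSE, p) else
      fac$cumulative[match(cn, fac$name)]
    cumulative[is.na(cumulative)] <- FALSE
  }
  with_seed(seed, lapply(seq_len(n_draws), function(i) {
    draw <- mu + matrix(stats::rnorm(n * p), n, p) * sdm
    draw[draw < 0] <- 0
    for (j in which(cumulative)) draw[, j] <- cummax(draw[, j])
    dimnames(draw) <- dimnames(mu)
    draw
  }))
}

#' Build teacher-forcing training windows
#'
#' Slides a daily window over every cultivation and augmentation draw. Each
#' sample holds the hourly feature matrix for the L predicted days, the
#' previous L days of growth labels as decoder input, and the target labels:
#' the previous-growth sequence shifted forward by one day, so the last
#' target position is the day after the previous window ends (the "next day"
#' selected during recursive simulation). Samples never mix days across
#' cultivations. The train/validation split is random at the sample level.
#'
#' @param cultivations List; each element a list with components `env` (an
#'   [env_series()]), `labels` (a `daily_labels` object) and optionally
#'   `draws` (augmented label sets from [augment_labels()]; defaults to the
#'   interpolated means only) and `id` (cultivation label).
#' @param memory_length Window length L in days.
#' @param split Fraction of samples assigned to the training set.
#' @param seed Integer seed for the split.
#' @param t_base Base temperature for the feature computation.
#' @return List with `train` and `val`: lists of window samples (each a list
#'   `features`, `prev`, `target`, `cultivation`, `draw`, `day`), plus
#'   `memory_length` and `factor_names`, of class `crop_windows`.
#' @export
make_training_windows <- function(cultivations, memory_length, split = 0.7,
                                  seed = 1L, t_base = 10) {
  L <- as.integer(memory_length)
  stopifnot(L >= 1L, split > 0, split <= 1)
  samples <- list()
  factor_names <- NULL
  for (ci in seq_along(cultivations)) {
    cu <- cultivations[[ci]]
    id <- if (!is.null(cu$id)) cu$id else as.character(ci)
    lab <- cu$labels
    stopifnot(inherits(lab, "daily_labels"))
    draws <- if (!is.null(cu$draws)) cu$draws else list(lab$mean)
    daily <- compute_daily_features(cu$env, t_base = t_base)
    n_env <- max(daily$day)
    lab_days <- lab$day
    factor_names <- colnames(lab$mean)
    # prev window: label days d..d+L-1; target: d+1..d+L; features end d+L
    d_min <- min(lab_days)
    d_max <- min(max(lab_days), n_env) - L
    if (d_max < d_min)
      stop("cultivation '", id, "' too short: needs at least ",
           L + 1L, " labeled days with environment coverage of day ",
           d_min + L, ", has labels ", min(lab_days), "..", max(lab_days),
           " and ", n_env, " environment days")
    feats <- lapply(d_min:d_max, function(d)
      build_feature_matrix(cu$env, end_day = d + L, memory_length = L,
                           daily = daily, t_base = t_base))
    names(feats) <- as.character(d_min:d_max)
    for (k in seq_along(draws)) {
      m <- draws[[k]]
      for (d in d_min:d_max) {
        prev_rows <- match(d:(d + L - 1L), lab_days)
        tgt_rows <- match((d + 1L):(d + L), lab_days)
        samples[[length(samples) + 1L]] <- list(
          features = feats[[as.character(d)]],
          prev = m[prev_rows, , drop = FALSE],
          target = m[tgt_rows, , drop = FALSE],
          cultivation = id, draw = k, day = d)
      }
    }
  }
  n <- length(samples)
  idx <- with_seed(seed, sample.int(n, size = max(1L, round(split * n))))
  structure(list(train = samples[idx],
                 val = if (length(idx) < n) samples[-idx] else list(),
                 memory_length = L, factor_names = factor_names),
            class = "crop_windows")
}

#' Read / write the growth CSV dialect (long format)
#'
#' Columns: `day`, `factor` (controlled vocabulary of [crop_factors()]),
#' `mean`, `sd`, `n_plants`.
#'
#' @param path File path.
#' @return `read_growth_csv()` returns a [growth_obs()].
#' @export
read_growth_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("day", "factor", "mean", "sd", "n_plants")
  if (!all(need %in% names(df)))
    stop("growth CSV must have columns ", paste(need, collapse = ", "))
  fac <- crop_factors()$name
  bad <- setdiff(unique(df$factor), fac)
  if (length(bad))
    stop("unknown growth factor(s): ", paste(bad, collapse = ", "))
  days <- sort(unique(df$day))
  mk <- function(col) {
    m <- matrix(NA_real_, length(days), length(fac),
                dimnames = list(NULL, fac))
    m[cbind(match(df$day, days), match(df$factor, fac))] <- df[[col]]
    m
  }
  np <- vapply(days, function(d) as.integer(df$n_plants[df$day == d][1]), 1L)
  growth_obs(days, mk("mean"), mk("sd"), np)
}

#' @rdname read_growth_csv
#' @param obs A [growth_obs()].
#' @export
write_growth_csv <- function(obs, path) {
  stopifnot(inherits(obs, "growth_obs"))
  fac <- colnames(obs$mean)
  df <- do.call(rbind, lapply(seq_along(obs$day), function(i)
    data.frame(day = obs$day[i], factor = fac, mean = obs$mean[i, ],
               sd = obs$sd[i, ], n_plants = obs$n_plants[i])))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
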