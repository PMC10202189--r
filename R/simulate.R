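#' Seed window from an initial growth state
#'
#' The rollout needs L previous days of growth; at cultivation start only the
#' initial factors exist, so the seed window holds the initial vector
#' constant over the first L days.
#'
#' @param init Named numeric vector of all growth factors (or a
#'   [growth_obs()], whose first observation is used).
#' @param memory_length L.
#' @param factor_names Required factor names.
#' @return `(L, n_factors)` matrix.
#' @export
initialize_state <- function(init, memory_length,
                             factor_names = crop_factors()$name) {
  if (inherits(init, "growth_obs")) init <- init$mean[1, ]
  missing <- setdiff(factor_names, names(init))
  if (length(missing))
    stop("initial state lacks factor(s): ", paste(missing, collapse = ", "))
  init <- init[factor_names]
  matrix(rep(init, each = memory_length), memory_length,
         length(factor_names), dimnames = list(NULL, factor_names))
}

#' Recursive daily growth simulation
#'
#' Rolls a trained model forward one day at a time from an initial growth
#' state and environment data only. Each step feeds the last L predicted
#' days and the hourly feature window ending on the next day; the last
#' position of each decoder's output sequence becomes that day's state,
#' which recursively replaces the previous growth input.
#'
#' With `guidance = TRUE` (default) the cumulative encoder inputs
#' (cumulative GDD and daily cumulative radiation) are always computed from
#' the measured environment. With `guidance = FALSE` they are reconstructed
#' from the model's own status outputs (its predicted cumulative GDD, and
#' daily radiation differenced from its predicted total cumulative
#' radiation), so guidance toggles exactly those two encoder columns.
#'
#' `sanitize = TRUE` clips negative predictions to zero and enforces
#' non-decreasing cumulative factors by running maximum; it is off by
#' default so the raw model behaviour (including possible mid-season dips)
#' is visible.
#'
#' @param model A fitted [attncrop] model.
#' @param env [env_series()] covering the seed window plus `n_days`.
#' @param init Initial growth state (vector or [growth_obs()]).
#' @param n_days Number of days to simulate.
#' @param guidance Replace cumulative encoder inputs with environment-derived
#'   values (default `TRUE`).
#' @param sanitize Post-process the trajectory (default `FALSE`).
#' @return data.frame of class `crop_simulation`: `day` (environment day
#'   index, starting after the L seed days) plus one column per factor.
#' @export
run_simulation <- function(model, env, init, n_days, guidance = TRUE,
                           sanitize = FALSE) {
  stopifnot(inherits(model, "attncrop"))
  cfg <- model$config
  L <- cfg$memory_length
  fac <- cfg$factor_names
  daily <- compute_daily_features(env)
  if (max(daily$day) < L + n_days)
    stop("environment covers ", max(daily$day), " days but the simulation ",
         "needs ", L + n_days, " (", L, " seed days + ", n_days, ")")
  seedw <- initialize_state(init, L, fac)
  states <- matrix(NA_real_, L + n_days, length(fac),
                   dimnames = list(NULL, fac))
  states[seq_len(L), ] <- seedw
  cum <- crop_factors()
  is_cum <- cum$cumulative[match(fac, cum$name)]
  for (t in (L + 1L):(L + n_days)) {
    dtab <- daily
    if (!guidance) {
      # rebuild the two cumulative encoder columns from predicted status
      known <- seq_len(t - 1L)
      cg <- states[known, "cum_gdd"]
      cr <- states[known, "cum_radiation"]
      dtab$cum_gdd[known] <- cg
      dtab$cum_gdd[t] <- cg[t - 1L]            # hold: day t not yet predicted
      dcr <- diff(c(0, cr)) * 1000             # MJ -> kJ per day
      dtab$daily_cum_radiation[known] <- pmax(0, dcr)
      dtab$daily_cum_radiation[t] <- max(0, dcr[t - 1L])
    }
    X <- build_feature_matrix(env, end_day = t, memory_length = L,
                              daily = dtab)
    Xs <- scale_transform(X, model$scaler, "features")
    Ps <- scale_transform(states[(t - L):(t - 1L), , drop = FALSE],
                          model$scaler, "factors")
    fw <- model_forward(model$params, cfg, Xs, Ps, 1L, model$norm,
                        train = FALSE)
    nxt <- numeric(length(fac))
    for (nm in names(cfg$decoder_map))
      nxt[cfg$decoder_map[[nm]]] <- fw$preds[[nm]][L, ]
    nxt <- scale_invert(nxt, model$scaler, "factors")
    if (!all(is.finite(nxt)))
      stop("non-finite prediction at day ", t)
    if (sanitize) {
      nxt <- pmax(nxt, 0)
      nxt[is_cum] <- pmax(nxt[is_cum], states[t - 1L, is_cum])
    }
    states[t, ] <- nxt
  }
  out <- data.frame(day = (L + 1L):(L + n_days))
  out <- cbind(out, as.data.frame(states[(L + 1L):(L + n_days), ,
                                         drop = FALSE]))
  attr(out, "guidance") <- guidance
  attr(out, "sanitize") <- sanitize
  attr(out, "seed_days") <- L
  class(out) <- c("crop_simulation", "data.frame")
  out
}

#' Write a simulated trajectory as CSV
#'
#' @param run A `crop_simulation`.
#' @param path File path.
#' @export
write_trajectory_csv <- function(run, path) {
  utils::write.csv(as.data.frame(run), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
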