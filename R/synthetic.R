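#' Cultivation scenario for the synthetic greenhouse
#'
#' Describes one cultivation: calendar placement, length, planting density and
#' the seasonal/diurnal climate curves (with noise scales) from which hourly
#' environment data are generated. Defaults emulate a temperate, climate-
#' controlled greenhouse.
#'
#' @param start_doy Day of year the cultivation starts.
#' @param n_days Cultivation length in days (>= 30).
#' @param density Planting density, plants m-2.
#' @param temp_mean Annual mean of the daily mean temperature, C.
#' @param temp_seasonal_amp Seasonal amplitude of the daily mean, C.
#' @param temp_diurnal_amp Diurnal (day/night) amplitude, C.
#' @param rh_mean,rh_amp Mean and diurnal amplitude of relative humidity, pct.
#' @param rad_max Clear-sky summer noon radiation inside the house, W m-2.
#' @param noise_temp,noise_rh Hourly additive noise SDs.
#' @param seed Integer seed for this scenario's random streams.
#' @param id Scenario label.
#' @return List of class `cultivation_scenario`.
#' @export
cultivation_scenario <- function(start_doy = 60L, n_days = 110L,
                                 density = 3.5, temp_mean = 22,
                                 temp_seasonal_amp = 2, temp_diurnal_amp = 5,
                                 rh_mean = 72, rh_amp = 10, rad_max = 550,
                                 noise_temp = 0.6, noise_rh = 2.5,
                                 seed = 1L, id = "scenario") {
  if (n_days < 30L) stop("n_days must be >= 30")
  if (density <= 0) stop("density must be positive")
  structure(list(start_doy = as.integer(start_doy), n_days = as.integer(n_days),
                 density = density, temp_mean = temp_mean,
                 temp_seasonal_amp = temp_seasonal_amp,
                 temp_diurnal_amp = temp_diurnal_amp, rh_mean = rh_mean,
                 rh_amp = rh_amp, rad_max = rad_max, noise_temp = noise_temp,
                 noise_rh = noise_rh, seed = as.integer(seed), id = id),
            class = "cultivation_scenario")
}

#' Default four-cultivation study: two seasons in each of two years
#'
#' Spring and autumn cultivations for two consecutive "years"; years differ in
#' their weather draws and slightly in their seasonal means, seasons differ
#' strongly in radiation and day length. Management (planting density) is held
#' constant across cultivations because density is not a model input.
#'
#' @param seed Base seed; each scenario derives its own stream from it.
#' @return List of four [cultivation_scenario()] objects.
#' @export
default_scenarios <- function(seed = 20L) {
  s <- as.integer(seed)
  list(
    cultivation_scenario(start_doy = 57L, n_days = 115L, temp_mean = 22.0,
                         seed = s + 1L, id = "y1_spring"),
    cultivation_scenario(start_doy = 299L, n_days = 91L, temp_mean = 21.5,
                         seed = s + 2L, id = "y1_autumn"),
    cultivation_scenario(start_doy = 67L, n_days = 110L, temp_mean = 22.4,
                         seed = s + 3L, id = "y2_spring"),
    cultivation_scenario(start_doy = 296L, n_days = 90L, temp_mean = 21.2,
                         seed = s + 4L, id = "y2_autumn"))
}

# seasonal curves shared by generation and tests
season_curve <- function(scenario, doy) {
  list(
    temp_daily_mean = scenario$temp_mean +
      scenario$temp_seasonal_amp * sin(2 * pi * (doy - 80) / 365),
    rad_factor = 0.65 + 0.35 * sin(2 * pi * (doy - 80) / 365),
    daylength = 12 + 3 * sin(2 * pi * (doy - 80) / 365))
}

#' Generate an hourly greenhouse environment series
#'
#' Sinusoidal diurnal temperature and humidity around seasonal means, with a
#' daylight-limited half-sine radiation curve scaled by season and a per-day
#' "cloudiness" factor; additive hourly noise on temperature and humidity.
#' Radiation is exactly zero at night. Deterministic under the scenario seed.
#'
#' @param scenario A [cultivation_scenario()].
#' @return An [env_series()] of `24 * n_days` records starting at midnight.
#' @export
generate_environment <- function(scenario) {
  stopifnot(inherits(scenario, "cultivation_scenario"))
  n <- scenario$n_days
  with_seed(scenario$seed, {
    doy <- ((scenario$start_doy + seq_len(n) - 2L) %% 365L) + 1L
    cur <- season_curve(scenario, doy)
    cloud <- stats::runif(n, 0.55, 1)          # per-day radiation factor
    day_anom <- stats::rnorm(n, 0, 0.7)        # per-day temperature anomaly
    temp <- rh <- rad <- numeric(24L * n)
    for (d in seq_len(n)) {
      h <- 0:23
      rows <- (d - 1L) * 24L + 1:24
      diurnal <- cos(2 * pi * (h - 14) / 24)
      temp[rows] <- cur$temp_daily_mean[d] + day_anom[d] +
        scenario$temp_diurnal_amp * diurnal +
        stats::rnorm(24, 0, scenario$noise_temp)
      rh[rows] <- scenario$rh_mean - scenario$rh_amp * diurnal +
        stats::rnorm(24, 0, scenario$noise_rh)
      dl <- cur$daylength[d]
      sunrise <- 12 - dl / 2
      frac <- (h + 0.5 - sunrise) / dl        # position within the light period
      shape <- ifelse(frac > 0 & frac < 1, sin(pi * frac), 0)
      rad[rows] <- scenario$rad_max * cur$rad_factor[d] * cloud[d] * shape
    }
    start <- as.POSIXct(as.Date("2020-01-01") + scenario$start_doy - 1L,
                        tz = "UTC")
    env_series(start + 3600 * (seq_len(24L * n) - 1L),
               temp, pmin(100, pmax(0, rh)), pmax(0, rad))
  })
}

#' Reference grower parameters
#'
#' Parameters of the minimal radiation-use-efficiency grower that produces
#' the synthetic "true" daily growth: Gompertz canopy (LAI), Beer-law light
#' interception, a fixed radiation-use efficiency, thermal-time dependent
#' partitioning to leaf/stem/petiole/fruit, per-organ dry-matter contents
#' (FW = DW / dmc) and specific dimensions, and a twice-weekly harvest rule.
#'
#' @param lai_init,lai_max Initial and maximum leaf area index.
#' @param c_plai Gompertz rate parameter (per degree-day).
#' @param t_base Base temperature for thermal time, C.
#' @param rue Radiation-use efficiency, g DW per MJ intercepted.
#' @param k_beer Beer-law extinction coefficient.
#' @param tau Greenhouse light transmissivity applied to outside-sensor
#'   radiation (dimensionless).
#' @param fruit_ts_on,fruit_ts_full Thermal times (degree-days) where fruit
#'   partitioning starts and reaches `fruit_frac_max`.
#' @param fruit_frac_max Maximum fraction of assimilate routed to fruit.
#' @param veg_split Leaf/stem/petiole split of vegetative assimilate
#'   (sums to 1).
#' @param dmc Named dry-matter contents per organ (0 < dmc < 1).
#' @param sla Specific leaf area, m2 per g leaf DW.
#' @param leaves_per_g Leaf (and petiole) count per g leaf DW.
#' @param node_cm_per_g,node_mm_per_g Summed node length (cm) and diameter
#'   (mm) per g stem DW.
#' @param node_spacing_cm Mean internode length, cm (gives nodes per stem).
#' @param n_stems Maintained stems per plant.
#' @param dw_per_fruit Dry weight of one harvested fruit, g.
#' @param fruit_h_cm,fruit_w_cm Height and width of one fruit, cm.
#' @param harvest_dow Days-of-week (0-6) on which harvest events occur.
#' @param harvest_frac Fraction of the on-plant fruit pool removed per event.
#' @param init_dw Named initial organ dry weights at transplanting, g.
#' @return List of class `reference_params`.
#' @export
reference_params <- function(lai_init = 0.1, lai_max = 3.5, c_plai = 0.0035,
                             t_base = 10, rue = 3.0, k_beer = 0.7, tau = 0.7,
                             fruit_ts_on = 350, fruit_ts_full = 800,
                             fruit_frac_max = 0.6,
                             veg_split = c(leaf = 0.5, stem = 0.3,
                                           petiole = 0.2),
                             dmc = c(leaf = 0.10, stem = 0.12,
                                     petiole = 0.09, fruit = 0.075),
                             sla = 0.020, leaves_per_g = 2,
                             node_cm_per_g = 3, node_mm_per_g = 0.8,
                             node_spacing_cm = 4.5, n_stems = 2,
                             dw_per_fruit = 12, fruit_h_cm = 7.5,
                             fruit_w_cm = 7,
                             harvest_dow = c(2L, 5L), harvest_frac = 0.5,
                             init_dw = c(leaf = 1.2, stem = 0.8,
                                         petiole = 0.3, fruit = 0)) {
  if (lai_init <= 0 || lai_max <= 0 || lai_init >= lai_max)
    stop("need 0 < lai_init < lai_max")
  if (abs(sum(veg_split) - 1) > 1e-9)
    stop("veg_split must sum to 1")
  if (any(dmc <= 0) || any(dmc >= 1))
    stop("dry-matter contents must lie in (0, 1)")
  structure(as.list(environment()), class = "reference_params")
}

#' Gompertz leaf area index over thermal time
#'
#' `LAI(TS) = LAI_max * exp(log(LAI_init / LAI_max) * exp(-C * TS))`:
#' equals `LAI_init` at TS = 0 and approaches `LAI_max` as TS grows.
#'
#' @param ts Thermal time, degree-days (>= 0); vectorized.
#' @param params A [reference_params()] (only the LAI fields are used).
#' @return LAI values.
#' @export
#' @examples
#' p <- reference_params()
#' gompertz_lai(0, p)     # lai_init
#' gompertz_lai(6000, p)  # ~ lai_max
gompertz_lai <- function(ts, params = reference_params()) {
  if (params$lai_init <= 0 || params$lai_max <= 0)
    stop("LAI parameters must be positive")
  if (any(ts < 0)) stop("thermal time must be >= 0")
  params$lai_max * exp(log(params$lai_init / params$lai_max) *
                         exp(-params$c_plai * ts))
}

#' Simulate reference "true" daily growth
#'
#' The minimal process-based grower behind the synthetic data: daily per-area
#' assimilate is radiation-use efficiency times Beer-law intercepted
#' radiation under the Gompertz canopy; assimilate is partitioned to organs
#' by thermal-time dependent fractions; fresh weights follow from dry-matter
#' contents, and counts/dimensions from specific-dimension parameters. Fruit
#' biomass moves to the cumulative harvest pools in twice-weekly events.
#'
#' @param env An [env_series()] covering the cultivation.
#' @param params A [reference_params()].
#' @param scenario The [cultivation_scenario()] (for planting density).
#' @return data.frame with `day`, the 21 growth factor columns of
#'   [crop_factors()], and bookkeeping columns `fruit_pool_dw` and
#'   `assimilate` used by conservation checks.
#' @export
simulate_reference_growth <- function(env, params = reference_params(),
                                      scenario) {
  stopifnot(inherits(params, "reference_params"))
  daily <- compute_daily_features(env, t_base = params$t_base)
  n <- nrow(daily)
  dw <- params$init_dw
  cum_harv_dw <- 0
  fac <- crop_factors()$name
  out <- matrix(0, n, length(fac), dimnames = list(NULL, fac))
  pool <- assim <- numeric(n)
  for (d in seq_len(n)) {
    ts <- daily$cum_gdd[d]
    lai <- gompertz_lai(ts, params)
    rad_mj <- daily$daily_cum_radiation[d] / 1000 * params$tau
    a <- params$rue * rad_mj * (1 - exp(-params$k_beer * lai)) /
      scenario$density                               # g DW per plant
    f_fruit <- min(params$fruit_frac_max,
                   max(0, (ts - params$fruit_ts_on) /
                         (params$fruit_ts_full - params$fruit_ts_on)) *
                     params$fruit_frac_max)
    gain <- c(params$veg_split * (1 - f_fruit), fruit = f_fruit) * a
    dw <- dw + gain[names(dw)]
    if ((d %% 7L) %in% params$harvest_dow && dw[["fruit"]] > 0) {
      rm_dw <- params$harvest_frac * dw[["fruit"]]
      dw[["fruit"]] <- dw[["fruit"]] - rm_dw
      cum_harv_dw <- cum_harv_dw + rm_dw
    }
    n_fruit <- cum_harv_dw / params$dw_per_fruit
    node_len <- params$node_cm_per_g * dw[["stem"]]
    out[d, ] <- c(
      cum_radiation = daily$cum_radiation[d],
      cum_gdd = ts,
      plant_height = node_len / params$n_stems / 100,
      max_nodes = node_len / params$n_stems / params$node_spacing_cm,
      leaf_area = params$sla * dw[["leaf"]],
      leaf_count = params$leaves_per_g * dw[["leaf"]],
      leaf_fw = dw[["leaf"]] / params$dmc[["leaf"]],
      leaf_dw = dw[["leaf"]],
      node_length = node_len,
      node_diameter = params$node_mm_per_g * dw[["stem"]],
      stem_count = params$n_stems,
      stem_fw = dw[["stem"]] / params$dmc[["stem"]],
      stem_dw = dw[["stem"]],
      petiole_count = params$leaves_per_g * dw[["leaf"]],
      petiole_fw = dw[["petiole"]] / params$dmc[["petiole"]],
      petiole_dw = dw[["petiole"]],
      fruit_height = params$fruit_h_cm * n_fruit,
      fruit_width = params$fruit_w_cm * n_fruit,
      harvest_count = n_fruit,
      harvest_fw = cum_harv_dw / params$dmc[["fruit"]],
      harvest_dw = cum_harv_dw)
    pool[d] <- dw[["fruit"]]
    assim[d] <- a
  }
  cbind(data.frame(day = daily$day), as.data.frame(out),
        fruit_pool_dw = pool, assimilate = assim)
}

#' Sample synthetic destructive observations from a truth table
#'
#' Picks `n_dates` evenly spaced sampling days (`round(i * n / n_dates)`),
#' perturbs the true factor values with multiplicative Gaussian noise of
#' coefficient of variation `cv`, sets the reported SDs to `cv * mean`, and
#' re-monotonizes cumulative factors across sampling days (a destructive
#' investigation cannot observe cumulative harvest decreasing).
#'
#' @param truth Output of [simulate_reference_growth()].
#' @param n_dates Number of sampling dates (default 5).
#' @param cv Coefficient of variation of the measurement noise.
#' @param seed Integer seed.
#' @param n_plants Plants measured per investigation.
#' @return A [growth_obs()].
#' @export
sample_destructive_observations <- function(truth, n_dates = 5L, cv = 0.08,
                                            seed = 1L, n_plants = 6L) {
  if (n_dates < 1L) stop("n_dates must be >= 1")
  fac <- crop_factors()
  n <- max(truth$day)
  days <- unique(pmax(1L, round(seq_len(n_dates) * n / n_dates)))
  m <- as.matrix(truth[match(days, truth$day), fac$name, drop = FALSE])
  with_seed(seed, {
    noise <- matrix(stats::rnorm(length(m), 0, cv), nrow(m), ncol(m))
    obs_mean <- pmax(m * (1 + noise), 0)
  })
  for (j in which(fac$cumulative)) obs_mean[, j] <- cummax(obs_mean[, j])
  # keep FW/DW physically ordered under independent noise
  for (org in c("leaf", "stem", "petiole", "harvest")) {
    fw <- paste0(org, "_fw"); dwc <- paste0(org, "_dw")
    obs_mean[, fw] <- pmax(obs_mean[, fw], obs_mean[, dwc])
  }
  growth_obs(days, obs_mean, cv * obs_mean, rep(as.integer(n_plants),
                                                length(days)))
}

#' Generate an on-disk synthetic dataset bundle
#'
#' For each scenario, writes the environment CSV, the destructive-observation
#' growth CSV and the daily truth table, plus a JSON manifest recording every
#' scenario's parameters and seeds.
#'
#' @param scenarios List of [cultivation_scenario()] objects.
#' @param dir Output directory (created if needed).
#' @param params A [reference_params()].
#' @param n_dates,cv,n_plants Passed to [sample_destructive_observations()].
#' @return Invisibly, a list per scenario with the in-memory `env`, `truth`,
#'   `obs` objects and the file paths written.
#' @export
generate_dataset <- function(scenarios, dir, params = reference_params(),
                             n_dates = 5L, cv = 0.08, n_plants = 6L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  manifest <- list()
  for (sc in scenarios) {
    env <- generate_environment(sc)
    truth <- simulate_reference_growth(env, params, sc)
    obs <- sample_destructive_observations(truth, n_dates = n_dates, cv = cv,
                                           seed = sc$seed + 1000L,
                                           n_plants = n_plants)
    paths <- c(env = file.path(dir, paste0("env_", sc$id, ".csv")),
               growth = file.path(dir, paste0("growth_", sc$id, ".csv")),
               truth = file.path(dir, paste0("truth_", sc$id, ".csv")))
    write_env_csv(env, paths[["env"]])
    write_growth_csv(obs, paths[["growth"]])
    utils::write.csv(truth, paths[["truth"]], row.names = FALSE, quote = FALSE)
    out[[sc$id]] <- list(scenario = sc, env = env, truth = truth, obs = obs,
                         paths = paths)
    manifest[[sc$id]] <- unclass(sc)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
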