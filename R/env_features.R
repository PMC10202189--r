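#' Hourly greenhouse environment series
#'
#' Constructs and validates an hourly environment series: strictly increasing
#' timestamps at exactly 1-h spacing, relative humidity in \[0, 100\] and
#' non-negative radiation. This is the cleaned container every downstream
#' feature computation consumes.
#'
#' @param timestamp POSIXct vector (UTC recommended), hourly.
#' @param temperature Air temperature, degrees C.
#' @param relative_humidity Relative humidity, percent.
#' @param radiation Shortwave radiation, W m-2.
#' @return A data.frame of class `env_series`.
#' @export
env_series <- function(timestamp, temperature, relative_humidity, radiation) {
  timestamp <- as.POSIXct(timestamp, tz = "UTC")
  n <- length(timestamp)
  stopifnot(length(temperature) == n, length(relative_humidity) == n,
            length(radiation) == n)
  if (n < 2L) stop("env_series needs at least two hourly records")
  dt <- diff(as.numeric(timestamp))
  if (any(dt != 3600))
    stop("timestamps must be strictly increasing with exact 1-h spacing; ",
         "first violation at record ", which(dt != 3600)[1] + 1L,
         " (use interpolate_missing_env() on gappy data)")
  if (anyNA(temperature) || anyNA(relative_humidity) || anyNA(radiation))
    stop("env_series cannot contain NA values; interpolate first")
  if (any(relative_humidity < 0 | relative_humidity > 100))
    stop("relative_humidity must lie in [0, 100]")
  if (any(radiation < 0))
    stop("radiation must be non-negative")
  out <- data.frame(timestamp = timestamp, temperature = temperature,
                    relative_humidity = relative_humidity,
                    radiation = radiation)
  class(out) <- c("env_series", "data.frame")
  out
}

#' Fill gaps in raw hourly environment records by linear interpolation
#'
#' Missing hours (absent rows) and NA readings are filled per variable by
#' one-dimensional linear interpolation between the nearest valid neighbours.
#' Leading or trailing gaps have no bracketing values and raise an error.
#'
#' @param raw data.frame with columns `timestamp`, `temperature`,
#'   `relative_humidity`, `radiation`; rows may be missing or contain NAs.
#' @return An [env_series()] with attribute `gap_fraction`: the per-variable
#'   fraction of hours that were filled.
#' @export
#' @examples
#' ts <- as.POSIXct("2020-03-01", tz = "UTC") + 3600 * (0:2)
#' raw <- data.frame(timestamp = ts[c(1, 3)], temperature = c(10, 20),
#'                   relative_humidity = c(60, 70), radiation = c(0, 100))
#' env <- interpolate_missing_env(raw)
#' env$temperature[2]  # midpoint: 15
interpolate_missing_env <- function(raw) {
  vars <- c("temperature", "relative_humidity", "radiation")
  if (!all(c("timestamp", vars) %in% names(raw)))
    stop("raw environment table must have columns timestamp, ",
         paste(vars, collapse = ", "))
  ts <- as.POSIXct(raw$timestamp, tz = "UTC")
  o <- order(ts)
  raw <- raw[o, ]
  ts <- ts[o]
  if (anyDuplicated(as.numeric(ts))) stop("duplicate timestamps in raw data")
  grid <- seq(ts[1], ts[length(ts)], by = 3600)
  hours <- as.numeric(grid)
  at <- as.numeric(ts)
  filled <- data.frame(timestamp = grid)
  gap_fraction <- numeric(0)
  for (v in vars) {
    y <- raw[[v]]
    ok <- !is.na(y)
    if (sum(ok) < 2L)
      stop("variable '", v, "' has fewer than two valid records")
    xo <- at[ok]
    if (xo[1] > hours[1] || xo[length(xo)] < hours[length(hours)]) {
      span <- if (xo[1] > hours[1]) {
        paste(format(grid[1]), "to", format(as.POSIXct(xo[1], tz = "UTC", origin = "1970-01-01")))
      } else {
        paste(format(as.POSIXct(xo[length(xo)], tz = "UTC", origin = "1970-01-01")),
              "to", format(grid[length(grid)]))
      }
      stop("leading/trailing gap for variable '", v, "' (", span,
           "): no bracketing values for linear interpolation")
    }
    yi <- stats::approx(xo, y[ok], xout = hours, method = "linear")$y
    known <- hours %in% xo[ok]
    gap_fraction[v] <- mean(!known)
    filled[[v]] <- yi
  }
  filled$relative_humidity <- pmin(100, pmax(0, filled$relative_humidity))
  filled$radiation <- pmax(0, filled$radiation)
  out <- env_series(filled$timestamp, filled$temperature,
                    filled$relative_humidity, filled$radiation)
  attr(out, "gap_fraction") <- gap_fraction
  out
}

#' Saturation vapour pressure (kPa)
#'
#' Clausius-Clapeyron form `0.6113 * exp(5423 * (1/273.15 - 1/(273.15 + T)))`;
#' at 0 degrees C the exponent vanishes and the value is the leading
#' coefficient, 0.6113 kPa.
#'
#' @param temperature Temperature in degrees C (> -273.15).
#' @return Saturation vapour pressure in kPa.
#' @export
#' @examples
#' compute_svp(0)    # 0.6113
#' compute_svp(25)
compute_svp <- function(temperature) {
  if (any(temperature <= -273.15))
    stop("temperature must exceed absolute zero (-273.15 C)")
  0.6113 * exp(5423 * (1 / 273.15 - 1 / (273.15 + temperature)))
}

#' Vapour-pressure deficit (kPa)
#'
#' `VPD = SVP(T) * (1 - RH/100)`: zero at saturation, equal to the saturation
#' vapour pressure in perfectly dry air.
#'
#' @param temperature Temperature in degrees C.
#' @param relative_humidity Relative humidity in percent, within \[0, 100\].
#' @return VPD in kPa.
#' @export
compute_vpd <- function(temperature, relative_humidity) {
  if (any(relative_humidity < 0 | relative_humidity > 100))
    stop("relative_humidity must lie in [0, 100]")
  compute_svp(temperature) * (1 - relative_humidity / 100)
}

#' Daily growing degree days
#'
#' Daily mean of the 24 hourly temperatures minus the base temperature,
#' floored at zero so that cold days contribute no (rather than negative)
#' thermal time and cumulative GDD is non-decreasing.
#'
#' @param env_day Numeric vector of exactly 24 hourly temperatures (C).
#' @param t_base Base temperature, degrees C (default 10).
#' @return Degree-days for the day (>= 0).
#' @export
#' @examples
#' compute_daily_gdd(rep(20, 24))  # 10
compute_daily_gdd <- function(env_day, t_base = 10) {
  if (length(env_day) != 24L)
    stop("env_day must contain exactly 24 hourly temperatures, got ",
         length(env_day))
  max(0, mean(env_day) - t_base)
}

#' Per-day derived environment features
#'
#' Aggregates an hourly [env_series()] to one row per complete calendar day:
#' \itemize{
#'   \item `dif`: mean day-period minus mean night-period temperature (C).
#'     The day period is, by default, the hours with radiation > 0;
#'     alternatively a fixed clock window.
#'   \item `daily_cum_radiation`: radiation integrated over the day with a
#'     1-h rectangle rule, kJ m-2 day-1.
#'   \item `daily_vpd`: VPD of the daily mean temperature and mean RH, kPa.
#'   \item `daily_gdd`, `cum_gdd`: growing degree days (floored) and their
#'     running sum.
#'   \item `cum_radiation`: running total radiation sum, MJ m-2.
#' }
#' Partial first/last days are excluded with a warning.
#'
#' @param env An [env_series()].
#' @param t_base Base temperature for GDD, degrees C.
#' @param day_night `"radiation"` (day = hours with radiation > 0) or
#'   `"clock"` (fixed window).
#' @param clock_day Integer hour range used when `day_night = "clock"`:
#'   hours `h` with `clock_day[1] <= h < clock_day[2]` are day.
#' @return data.frame with one row per complete day, ordered; columns
#'   `day` (1-based index), `date`, `dif`, `daily_cum_radiation`,
#'   `daily_vpd`, `daily_gdd`, `cum_gdd`, `cum_radiation`.
#' @export
compute_daily_features <- function(env, t_base = 10,
                                   day_night = c("radiation", "clock"),
                                   clock_day = c(6L, 18L)) {
  day_night <- match.arg(day_night)
  stopifnot(inherits(env, "env_series"))
  date <- as.Date(env$timestamp, tz = "UTC")
  hour <- as.integer(format(env$timestamp, "%H", tz = "UTC"))
  counts <- table(date)
  complete <- names(counts)[counts == 24L]
  if (length(complete) < length(counts))
    warning("excluding ", length(counts) - length(complete),
            " partial day(s) at the series boundary")
  keep <- date %in% as.Date(complete)
  date <- date[keep]; hour <- hour[keep]
  temp <- env$temperature[keep]
  rh <- env$relative_humidity[keep]
  rad <- env$radiation[keep]
  udays <- sort(unique(date))
  n <- length(udays)
  if (n == 0L) stop("no complete days in the environment series")
  out <- data.frame(day = seq_len(n), date = udays,
                    dif = NA_real_, daily_cum_radiation = NA_real_,
                    daily_vpd = NA_real_, daily_gdd = NA_real_)
  for (i in seq_len(n)) {
    sel <- date == udays[i]
    ti <- temp[sel]; ri <- rad[sel]; hi <- hour[sel]; rhi <- rh[sel]
    is_day <- if (day_night == "radiation") ri > 0 else
      (hi >= clock_day[1] & hi < clock_day[2])
    out$dif[i] <- if (any(is_day) && any(!is_day))
      mean(ti[is_day]) - mean(ti[!is_day]) else 0
    out$daily_cum_radiation[i] <- sum(ri) * 3600 / 1000  # W m-2 h -> kJ m-2
    out$daily_vpd[i] <- compute_vpd(mean(ti), mean(rhi))
    out$daily_gdd[i] <- compute_daily_gdd(ti, t_base = t_base)
  }
  out$cum_gdd <- cumsum(out$daily_gdd)
  out$cum_radiation <- cumsum(out$daily_cum_radiation) / 1000  # kJ -> MJ
  out
}

#' Assemble the hourly model-input feature window
#'
#' Builds the `(24 * memory_length, 7)` encoder input for the window of
#' `memory_length` days ending at `end_day`. Columns follow the fixed order
#' of [env_feature_names()]; the four daily-resolution features are constant
#' across the 24 rows of their day.
#'
#' @param env An [env_series()].
#' @param end_day Day index (as in `compute_daily_features(env)$day`) of the
#'   last day in the window.
#' @param memory_length Window length L in days.
#' @param daily Optional precomputed daily feature table (output of
#'   [compute_daily_features()]); pass a modified table to override the
#'   cumulative columns, e.g. for guidance-off simulation.
#' @param t_base Base temperature used when `daily` is computed here.
#' @return Numeric matrix `(24 * memory_length, 7)` with attribute
#'   `day_index` giving the day label of each row.
#' @export
build_feature_matrix <- function(env, end_day, memory_length, daily = NULL,
                                 t_base = 10) {
  stopifnot(memory_length >= 1L)
  if (is.null(daily)) daily <- compute_daily_features(env, t_base = t_base)
  first <- end_day - memory_length + 1L
  if (first < min(daily$day) || end_day > max(daily$day))
    stop("insufficient environment history: window needs days ", first,
         "..", end_day, " but the first available day is ", min(daily$day),
         " and the last is ", max(daily$day))
  days <- first:end_day
  date <- as.Date(env$timestamp, tz = "UTC")
  L <- memory_length
  out <- matrix(NA_real_, nrow = 24L * L, ncol = 7L,
                dimnames = list(NULL, env_feature_names()))
  day_index <- rep(days, each = 24L)
  for (j in seq_along(days)) {
    d <- daily[daily$day == days[j], ]
    sel <- which(date == d$date)
    if (length(sel) != 24L)
      stop("day ", days[j], " does not have 24 hourly records")
    rows <- (j - 1L) * 24L + 1:24
    out[rows, "temperature"] <- env$temperature[sel]
    out[rows, "relative_humidity"] <- env$relative_humidity[sel]
    out[rows, "radiation"] <- env$radiation[sel]
    out[rows, "dif"] <- d$dif
    out[rows, "daily_cum_radiation"] <- d$daily_cum_radiation
    out[rows, "cum_gdd"] <- d$cum_gdd
    out[rows, "daily_vpd"] <- d$daily_vpd
  }
  attr(out, "day_index") <- day_index
  out
}

#' Read / write the environment CSV dialect
#'
#' Columns: `timestamp` (ISO 8601, hourly), `temperature_c`,
#' `relative_humidity_pct`, `radiation_w_m2`. The reader validates hourly
#' spacing via [env_series()].
#'
#' @param path File path.
#' @return `read_env_csv()` returns an [env_series()].
#' @export
read_env_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "temperature_c", "relative_humidity_pct",
            "radiation_w_m2")
  if (!all(need %in% names(df)))
    stop("environment CSV must have columns ", paste(need, collapse = ", "))
  env_series(as.POSIXct(df$timestamp, tz = "UTC",
                        tryFormats = c("%Y-%m-%dT%H:%M:%SZ",
                                       "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M")),
             df$temperature_c, df$relative_humidity_pct, df$radiation_w_m2)
}

#' @rdname read_env_csv
#' @param env An [env_series()].
#' @export
write_env_csv <- function(env, path) {
  stopifnot(inherits(env, "env_series"))
  df <- data.frame(
    timestamp = format(env$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    temperature_c = env$temperature,
    relative_humidity_pct = env$relative_humidity,
    radiation_w_m2 = env$radiation)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
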