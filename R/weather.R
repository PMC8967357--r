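#' @title Weather series input, downscaling, and synthesis
#' @name weather
#' @description Hourly weather drives the simulation clock: air
#'   temperature (degC), shortwave radiation (W m^-2), relative humidity
#'   (%), wind speed (m s^-1) and ambient CO2 (umol mol^-1). Daily input
#'   is downscaled to hourly; a stochastic synthesizer emulates two
#'   contrasting winter climates so the cold-stress pathways can be
#'   exercised without external data.
NULL

HOURLY_COLS <- c("timestamp", "T_air", "solar", "RH", "wind", "CO2")
DAILY_COLS  <- c("date", "T_max", "T_min", "solar_total", "RH_mean", "wind_mean")

new_weather_series <- function(df, cadence = c("hourly", "daily")) {
  cadence <- match.arg(cadence)
  structure(df, class = c("weather_series", "data.frame"),
            cadence = cadence)
}

#' Cadence of a weather series
#' @param w a `weather_series`.
#' @return `"hourly"` or `"daily"`.
#' @export
weather_cadence <- function(w) attr(w, "cadence")

#' Read a weather CSV
#'
#' Accepts either hourly files with columns
#' `timestamp,T_air,solar,RH,wind,CO2` (ISO-8601 timestamps, strict 1-h
#' step) or daily files with columns
#' `date,T_max,T_min,solar_total,RH_mean,wind_mean` (solar_total in
#' MJ m^-2 d^-1). Daily series are flagged for downscaling via
#' [downscale_daily_to_hourly()]. Units are fixed as listed; there is no
#' auto-detection.
#'
#' @param path CSV path.
#' @param tz timezone for timestamps (default UTC; local solar time is
#'   assumed throughout).
#' @return A `weather_series` data.frame; check [weather_cadence()].
#' @export
read_weather <- function(path, tz = "UTC") {
  if (!file.exists(path)) stop("weather file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(HOURLY_COLS %in% names(df))) {
    df <- df[HOURLY_COLS]
    df$timestamp <- as.POSIXct(df$timestamp, tz = tz,
                               tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                              "%Y-%m-%d %H:%M:%S",
                                              "%Y-%m-%d %H:%M"))
    if (anyNA(df$timestamp))
      stop("unparseable timestamp at row ",
           which(is.na(df$timestamp))[1])
    validate_hourly(df)
    new_weather_series(df, "hourly")
  } else if (all(DAILY_COLS %in% names(df))) {
    df <- df[DAILY_COLS]
    df$date <- as.Date(df$date)
    if (anyNA(df$date)) stop("unparseable date at row ",
                             which(is.na(df$date))[1])
    validate_daily(df)
    new_weather_series(df, "daily")
  } else {
    stop("weather CSV must contain columns ",
         paste(HOURLY_COLS, collapse = ","), " (hourly) or ",
         paste(DAILY_COLS, collapse = ","), " (daily); missing: ",
         paste(setdiff(HOURLY_COLS, names(df)), collapse = ","))
  }
}

validate_hourly <- function(df) {
  bad <- function(cond, msg) {
    i <- which(cond)[1]
    if (!is.na(i)) stop("weather format error at row ", i, ": ", msg,
                        call. = FALSE)
  }
  if (nrow(df) > 1) {
    dt <- diff(as.numeric(df$timestamp))
    i <- which(dt != 3600)[1]
    if (!is.na(i))
      stop("weather format error at row ", i + 1,
           ": timestamps must increase at a fixed 1-h step", call. = FALSE)
  }
  bad(df$RH < 0 | df$RH > 100, "RH outside [0,100]")
  bad(df$wind < 0, "negative wind speed")
  bad(df$solar < 0, "negative solar radiation")
  bad(df$CO2 <= 0, "non-positive CO2")
  invisible(df)
}

validate_daily <- function(df) {
  i <- which(df$T_max < df$T_min)[1]
  if (!is.na(i)) stop("weather format error at row ", i,
                      ": T_max < T_min", call. = FALSE)
  if (nrow(df) > 1) {
    i <- which(diff(as.numeric(df$date)) <= 0)[1]
    if (!is.na(i)) stop("weather format error at row ", i + 1,
                        ": dates must strictly increase", call. = FALSE)
  }
  i <- which(df$RH_mean < 0 | df$RH_mean > 100)[1]
  if (!is.na(i)) stop("weather format error at row ", i,
                      ": RH outside [0,100]", call. = FALSE)
  invisible(df)
}

# --- solar geometry (local solar time convention) ---------------------------

solar_declination <- function(doy) {
  -23.44 * pi / 180 * cos(2 * pi * (doy + 10) / 365.25)
}

#' Daylength from solar declination
#' @param latitude degrees north, in \[-90, 90\].
#' @param doy day of year.
#' @return hours of daylight.
#' @export
daylength <- function(latitude, doy) {
  stopifnot(latitude >= -90, latitude <= 90)
  phi <- latitude * pi / 180
  dec <- solar_declination(doy)
  x <- pmin(pmax(-tan(phi) * tan(dec), -1), 1)
  24 / pi * acos(x)
}

cos_zenith <- function(latitude, doy, hour) {
  phi <- latitude * pi / 180
  dec <- solar_declination(doy)
  sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(pi * (hour - 12) / 12)
}

# --- daily -> hourly downscaling --------------------------------------------

#' Downscale a daily weather series to hourly
#'
#' Temperature follows a half-sine rise from `T_min` at dawn to `T_max`
#' at 14:00 solar time, then an exponential night decay back toward
#' `T_min`; daily shortwave `solar_total` (MJ m^-2) is distributed over
#' the daylength by a normalized half-sine, so the hourly integral
#' recovers the daily total exactly. RH and wind are held at their daily
#' means; hourly min/max temperature reproduce `T_min`/`T_max`.
#'
#' @param daily a daily `weather_series` (from [read_weather()]) or a
#'   data.frame with the daily columns.
#' @param latitude site latitude in degrees (drives dawn hour and
#'   daylength).
#' @param co2 ambient CO2 to fill (umol mol^-1) when the daily file
#'   carries none.
#' @return An hourly `weather_series` with 24 records per day.
#' @export
downscale_daily_to_hourly <- function(daily, latitude, co2 = 400) {
  stopifnot(latitude >= -90, latitude <= 90)
  if (nrow(daily) == 0) stop("empty daily series")
  validate_daily(daily)
  n <- nrow(daily)
  hours <- 0:23
  out <- vector("list", n)
  night_decay <- 0.3   # h^-1; night temperature relaxation rate
  for (i in seq_len(n)) {
    doy <- as.integer(strftime(daily$date[i], "%j"))
    dl <- daylength(latitude, doy)
    sunrise <- 12 - dl / 2
    h_dawn <- min(max(round(sunrise), 1), 11)
    h_peak <- 14
    tmin <- daily$T_min[i]; tmax <- daily$T_max[i]
    temp <- numeric(24)
    day_idx <- hours >= h_dawn & hours <= h_peak
    temp[day_idx] <- tmin + (tmax - tmin) *
      sin(pi / 2 * (hours[day_idx] - h_dawn) / (h_peak - h_dawn))
    # night: decay from Tmax toward Tmin; pre-dawn hours continue the
    # previous evening's decay (same-day Tmin target keeps the daily
    # min/max round trip exact)
    post <- hours > h_peak
    temp[post] <- tmin + (tmax - tmin) * exp(-night_decay * (hours[post] - h_peak))
    pre <- hours < h_dawn
    temp[pre] <- tmin + (tmax - tmin) *
      exp(-night_decay * (hours[pre] + 24 - h_peak))
    # solar: half-sine weights on hour midpoints within daylight
    mid <- hours + 0.5
    w <- sin(pi * (mid - sunrise) / dl)
    w[mid <= sunrise | mid >= sunrise + dl] <- 0
    w[w < 0] <- 0
    if (sum(w) == 0) w[13] <- 1
    solar <- w / sum(w) * daily$solar_total[i] * 1e6 / 3600  # W m^-2
    out[[i]] <- data.frame(
      timestamp = as.POSIXct(daily$date[i], tz = "UTC") + hours * 3600,
      T_air = temp, solar = solar,
      RH = rep(daily$RH_mean[i], 24),
      wind = rep(daily$wind_mean[i], 24),
      CO2 = rep(co2, 24)
    )
  }
  new_weather_series(do.call(rbind, out), "hourly")
}

# --- synthetic climate ------------------------------------------------------

climate_profiles <- function() {
  list(
    subtropical = list(   # Gosan-like humid subtropical, mild winter
      latitude = 33.3, t_mean = 16.5, t_amp = 9.5, diurnal_half = 3,
      noise_sd = 2.0, noise_phi = 0.6,
      rh_mean = 70, wind_mean = 3.0, tau_mean = 0.55, tau_sd = 0.12
    ),
    continental = list(   # Chuncheon-like humid continental, cold winter
      latitude = 37.9, t_mean = 10.0, t_amp = 17.5, diurnal_half = 4,
      noise_sd = 3.0, noise_phi = 0.6,
      rh_mean = 65, wind_mean = 2.5, tau_mean = 0.55, tau_sd = 0.12
    )
  )
}

#' Synthesize an hourly weather series
#'
#' Stochastic weather generator emulating either a humid-subtropical
#' mild-winter site (`"subtropical"`, latitude 33.3 N) or a
#' humid-continental cold-winter site (`"continental"`, latitude
#' 37.9 N). Daily mean temperature is an annual sinusoid (coldest
#' mid-January) plus AR(1) residual noise; a diurnal cosine (warmest at
#' 14:00 solar) is superimposed. Shortwave is clear-sky radiation from
#' solar geometry scaled by an AR(1) daily transmissivity; RH varies
#' diurnally against temperature; radiation is zero when the sun is
#' below the horizon. At default severity the continental profile
#' delivers January minima below -10 degC with frost events below
#' -15 degC each winter, while the subtropical profile never reaches
#' -5 degC, so cold-damage mortality is exercised only in the
#' continental climate.
#'
#' @param profile `"subtropical"` or `"continental"`.
#' @param years number of complete calendar years to generate (>= 1).
#' @param seed integer RNG seed; the same seed reproduces the series
#'   bit-for-bit. The caller's RNG state is left untouched.
#' @param severity scalar (default 1) multiplying the seasonal
#'   temperature amplitude; > 1 deepens winter cold.
#' @param start_year first calendar year (default 2001).
#' @param co2 ambient CO2 (umol mol^-1) to fill, a scalar.
#' @return An hourly `weather_series`.
#' @examples
#' w <- synthesize_weather("subtropical", years = 1, seed = 42)
#' range(w$T_air)
#' @export
synthesize_weather <- function(profile = c("subtropical", "continental"),
                               years, seed, severity = 1,
                               start_year = 2001, co2 = 400) {
  profile <- match.arg(profile)
  stopifnot(years >= 1, severity > 0)
  p <- climate_profiles()[[profile]]

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", start_year), tz = "UTC")
  t1 <- as.POSIXct(sprintf("%d-12-31 23:00:00", start_year + years - 1),
                   tz = "UTC")
  ts <- seq(t0, t1, by = 3600)
  n_days <- length(ts) / 24
  doy_d <- as.integer(strftime(ts[seq(1, length(ts), by = 24)], "%j"))

  ar1 <- function(n, sd, phi) {
    e <- stats::rnorm(n, sd = sd * sqrt(1 - phi^2))
    stats::filter(e, phi, method = "recursive",
                  init = stats::rnorm(1, sd = sd))
  }
  t_resid <- as.numeric(ar1(n_days, p$noise_sd, p$noise_phi))
  tau <- pmin(pmax(p$tau_mean + as.numeric(ar1(n_days, p$tau_sd, 0.5)),
                   0.2), 0.78)
  wind_d <- stats::rlnorm(n_days, log(p$wind_mean) - 0.18, 0.6)

  t_clim <- p$t_mean - p$t_amp * severity *
    cos(2 * pi * (doy_d - 15) / 365.25)
  t_daily <- t_clim + t_resid

  hour <- rep(0:23, n_days)
  di <- rep(seq_len(n_days), each = 24)
  shape <- cos(2 * pi * (hour - 14) / 24)        # +1 at 14:00, -1 at 02:00
  T_air <- t_daily[di] + p$diurnal_half * shape

  cz <- cos_zenith(p$latitude, rep(doy_d, each = 24), hour + 0.5)
  solar <- ifelse(cz > 0, 1100 * cz * tau[di], 0)

  RH <- pmin(pmax(p$rh_mean - 12 * shape - 1.5 * t_resid[di] +
                    stats::rnorm(length(ts), sd = 3), 5), 100)
  wind <- wind_d[di]

  new_weather_series(data.frame(
    timestamp = ts, T_air = T_air, solar = solar, RH = RH,
    wind = wind, CO2 = rep(co2, length(ts))
  ), "hourly")
}

# --- CO2 scenario trajectories ----------------------------------------------

#' CO2 scenario trajectory
#'
#' Piecewise-linear CO2 concentration over calendar time, anchored at
#' scenario projection years (e.g. decadal RCP concentration tables).
#'
#' @param anchors named numeric vector, names = years, values =
#'   concentrations (umol mol^-1); years must strictly increase and
#'   concentrations be positive.
#' @param scenario label, e.g. `"RCP4.5"`.
#' @return A `co2_trajectory` object for [co2_at()].
#' @examples
#' tr <- co2_trajectory(c(`2020` = 400, `2030` = 420), "demo")
#' co2_at(tr, 2025)
#' @export
co2_trajectory <- function(anchors, scenario = "custom") {
  yrs <- as.numeric(names(anchors))
  if (anyNA(yrs)) stop("anchor names must be numeric years")
  if (is.unsorted(yrs, strictly = TRUE)) stop("anchor years must strictly increase")
  if (any(anchors <= 0)) stop("CO2 concentrations must be positive")
  structure(list(years = yrs, co2 = as.numeric(anchors),
                 scenario = scenario), class = "co2_trajectory")
}

#' Interpolate a CO2 trajectory
#'
#' @param trajectory a [co2_trajectory()].
#' @param t decimal year (e.g. 2025.5), `Date`, or `POSIXct`; must fall
#'   within the anchor range (no extrapolation).
#' @return CO2 concentration (umol mol^-1); exact at anchors.
#' @export
co2_at <- function(trajectory, t) {
  stopifnot(inherits(trajectory, "co2_trajectory"))
  ty <- decimal_year(t)
  if (any(ty < trajectory$years[1] | ty > trajectory$years[length(trajectory$years)]))
    stop("time outside CO2 anchor range [", trajectory$years[1], ", ",
         trajectory$years[length(trajectory$years)], "]")
  stats::approx(trajectory$years, trajectory$co2, xout = ty)$y
}

decimal_year <- function(t) {
  if (inherits(t, "POSIXct") || inherits(t, "Date")) {
    yr <- as.integer(strftime(t, "%Y"))
    doy <- as.integer(strftime(t, "%j"))
    ndays <- ifelse(yr %% 4 == 0 & (yr %% 100 != 0 | yr %% 400 == 0), 366, 365)
    yr + (doy - 1) / ndays
  } else {
    as.numeric(t)
  }
}
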