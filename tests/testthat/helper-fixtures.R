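# Shared fixtures: memoised season runs and constant-weather builders,
# so expensive simulations are computed once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

base_config <- function(...) {
  garlic_config(simulation = list(planting_date = "2001-10-01"), ...)
}

subtropical_weather <- function(seed = 1) {
  cached(paste0("w_sub_", seed),
         synthesize_weather("subtropical", years = 2, seed = seed))
}

continental_weather <- function(seed = 3) {
  cached(paste0("w_con_", seed),
         synthesize_weather("continental", years = 2, seed = seed))
}

subtropical_run <- function(seed = 1) {
  cached(paste0("run_sub_", seed), run_season(subtropical_weather(seed), base_config()))
}

continental_run <- function(seed = 3) {
  cached(paste0("run_con_", seed), run_season(continental_weather(seed), base_config()))
}

# constant-condition hourly weather: fixed temperature, clear-sky-like
# half-sine solar by day, benign RH/wind
constant_weather <- function(t_air, days, start = "2001-10-01",
                             solar_peak = 600, co2 = 400) {
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  ts <- seq(t0, by = 3600, length.out = days * 24)
  hour <- rep(0:23, days)
  w <- sin(pi * (hour - 6) / 12)
  solar <- ifelse(hour >= 6 & hour <= 18, solar_peak * pmax(w, 0), 0)
  structure(data.frame(timestamp = ts, T_air = t_air, solar = solar,
                       RH = 70, wind = 2, CO2 = co2),
            class = c("weather_series", "data.frame"), cadence = "hourly")
}

write_weather_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
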