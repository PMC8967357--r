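test_that("hourly CSV round-trips through read_weather", {
  w <- constant_weather(10, days = 1)
  w$timestamp <- format(w$timestamp, "%Y-%m-%dT%H:%M:%S")
  names(w)[names(w) == "solar"] <- "solar"
  path <- write_weather_csv(as.data.frame(w))
  rd <- read_weather(path)
  expect_equal(nrow(rd), 24)
  expect_identical(weather_cadence(rd), "hourly")
  expect_equal(rd$T_air, rep(10, 24))
})

test_that("invalid hourly input raises format errors naming the row", {
  w <- as.data.frame(constant_weather(10, days = 1))
  w$timestamp <- format(w$timestamp, "%Y-%m-%dT%H:%M:%S")
  w$RH[5] <- 120
  expect_error(read_weather(write_weather_csv(w)), "row 5.*RH")
  w$RH[5] <- 70
  w2 <- w[c(1:10, 12:24), ]   # missing hour 11
  expect_error(read_weather(write_weather_csv(w2)), "1-h step")
  expect_error(read_weather(write_weather_csv(w[, -2])), "missing")
})

test_that("daily CSV is flagged for downscaling", {
  d <- data.frame(date = as.Date("2001-01-01") + 0:2,
                  T_max = c(10, 12, 8), T_min = c(2, 3, -1),
                  solar_total = c(12, 15, 9), RH_mean = 70, wind_mean = 2)
  rd <- read_weather(write_weather_csv(d))
  expect_identical(weather_cadence(rd), "daily")
  expect_equal(nrow(rd), 3)
  d$T_max[2] <- 1   # below T_min
  expect_error(read_weather(write_weather_csv(d)), "row 2.*T_max")
})

test_that("downscaling preserves daily min, max and solar integral", {
  d <- data.frame(date = as.Date("2001-03-10"), T_max = 10, T_min = 0,
                  solar_total = 20, RH_mean = 70, wind_mean = 2)
  h <- downscale_daily_to_hourly(d, latitude = 33.3)
  expect_equal(nrow(h), 24)
  expect_equal(min(h$T_air), 0, tolerance = 0.01)
  expect_equal(max(h$T_air), 10, tolerance = 0.01)
  expect_equal(sum(h$solar) * 3600 / 1e6, 20, tolerance = 0.2)
  # monotone rise from dawn to the 14:00 peak
  dawn <- which.min(h$T_air)
  expect_equal(which.max(h$T_air), 15)  # hour 14 (1-based index 15)
  expect_true(all(diff(h$T_air[dawn:15]) >= 0))
})

test_that("degenerate amplitude gives a flat day and empty input errors", {
  d <- data.frame(date = as.Date("2001-06-01"), T_max = 10, T_min = 10,
                  solar_total = 25, RH_mean = 60, wind_mean = 1)
  h <- downscale_daily_to_hourly(d, latitude = 33.3)
  expect_equal(h$T_air, rep(10, 24))
  expect_error(downscale_daily_to_hourly(d[0, ], 33.3), "empty")
})

test_that("downscale-aggregate round trip holds across random days", {
  set.seed(101)
  n <- 250
  d <- data.frame(
    date = as.Date("2001-01-01") + seq_len(n) - 1,
    T_min = runif(n, -15, 20), solar_total = runif(n, 2, 30),
    RH_mean = runif(n, 30, 95), wind_mean = runif(n, 0, 8)
  )
  d$T_max <- d$T_min + runif(n, 0, 15)
  h <- downscale_daily_to_hourly(d, latitude = 37)
  day <- rep(seq_len(n), each = 24)
  expect_equal(as.vector(tapply(h$T_air, day, min)), d$T_min, tolerance = 0.01)
  expect_equal(as.vector(tapply(h$T_air, day, max)), d$T_max, tolerance = 0.01)
  tot <- as.vector(tapply(h$solar, day, sum)) * 3600 / 1e6
  expect_true(all(abs(tot - d$solar_total) / d$solar_total < 0.01))
  expect_true(all(h$solar >= 0))
})

test_that("synthetic weather is reproducible and profile contracts hold", {
  w1 <- synthesize_weather("continental", years = 1, seed = 7)
  w2 <- synthesize_weather("continental", years = 1, seed = 7)
  expect_identical(w1, w2)
  w3 <- synthesize_weather("continental", years = 1, seed = 8)
  expect_false(identical(w1$T_air, w3$T_air))

  # continental: cold-damage pathway exercised each winter
  for (seed in 1:3) {
    wc <- synthesize_weather("continental", years = 1, seed = seed)
    jan <- wc[strftime(wc$timestamp, "%m") == "01", ]
    tmin <- tapply(jan$T_air, as.Date(jan$timestamp), min)
    expect_lt(mean(tmin), -10)
    expect_gte(sum(wc$T_air < -15), 1)
  }
  # subtropical: cold-damage pathway never triggered
  for (seed in 1:3) {
    ws <- synthesize_weather("subtropical", years = 1, seed = seed)
    expect_equal(sum(ws$T_air < -5), 0)
    jan <- ws[strftime(ws$timestamp, "%m") == "01", ]
    expect_gt(mean(tapply(jan$T_air, as.Date(jan$timestamp), min)), 0)
  }
})

test_that("synthetic monthly means track the profile climatology", {
  w <- synthesize_weather("subtropical", years = 10, seed = 11)
  mo <- as.integer(strftime(w$timestamp, "%m"))
  doy <- as.integer(strftime(w$timestamp, "%j"))
  clim <- 16.5 - 9.5 * cos(2 * pi * (doy - 15) / 365.25)
  dev <- tapply(w$T_air - clim, mo, mean)
  expect_true(all(abs(dev) < 1))
  expect_true(all(w$solar >= 0))
  expect_true(all(w$RH >= 0 & w$RH <= 100))
  expect_true(all(w$wind >= 0))
  # radiation zero when the sun is below the horizon (night hours)
  night <- as.integer(strftime(w$timestamp, "%H")) %in% c(0, 23)
  expect_true(all(w$solar[night] == 0))
})

test_that("CO2 trajectories interpolate linearly between anchors", {
  tr <- co2_trajectory(c(`2020` = 400, `2030` = 420), "demo")
  expect_equal(co2_at(tr, 2025), 410)
  expect_equal(co2_at(tr, 2020), 400)
  tr3 <- co2_trajectory(c(`2020` = 400, `2030` = 420, `2040` = 450))
  expect_equal(co2_at(tr3, 2035), 435)
  expect_error(co2_at(tr3, 2050), "outside")
  expect_error(co2_trajectory(c(`2030` = 400, `2020` = 420)), "increase")
  expect_error(co2_trajectory(c(`2020` = -1, `2030` = 420)), "positive")
  expect_equal(co2_at(tr3, as.Date("2030-01-01")), 420)
})
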