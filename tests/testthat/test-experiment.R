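test_that("scan designs enumerate the planting-date x weather factorial", {
  expect_equal(default_planting_doys(), seq(240L, 350L, 10L))
  expect_length(default_planting_doys(), 12)
  expect_equal(nrow(build_scan(weather_ids = 1:10)), 120)
  expect_equal(nrow(build_scan(weather_ids = 1:80)), 960)
  expect_equal(nrow(build_scan(240, "a")), 1)
  g <- build_scan(c(240, 250), c("x", "y"))
  expect_setequal(paste(g$doy, g$weather_id), c("240 x", "250 x", "240 y", "250 y"))
})

test_that("fresh yield converts dry bulb mass at the bulb moisture content", {
  expect_equal(fresh_yield(3, 1, 0.85) * 1000, 20)   # 3 g dry -> 20 g fresh
  expect_equal(fresh_yield(3, 50, 0.85), 1.0)        # 1 kg m^-2
  expect_equal(fresh_yield(3, 50, 0), 3 * 50 / 1000) # moisture 0: fresh = dry
  expect_error(fresh_yield(3, 50, 1), "moisture")
  expect_error(fresh_yield(3, 50, 1.2), "moisture")
})

test_that("optimal planting picks the argmax DOY with earliest-date ties", {
  res <- data.frame(weather_id = "w1", doy = c(240, 250, 260),
                    fresh_yield = c(5, 7, 6))
  opt <- optimal_planting(res)
  expect_equal(opt$per_replicate$opt_doy, 250)
  res$fresh_yield <- c(5, 7, 7)                      # tie -> earlier DOY
  expect_equal(optimal_planting(res)$per_replicate$opt_doy, 250)
})

test_that("period grouping pools decade windows into multi-sample points", {
  windows <- seq(2020, 2090, 10)
  ids <- as.vector(outer(windows, 1:10, function(w, r) sprintf("%d_%d", w, r)))
  expect_length(ids, 80)
  scan <- build_scan(weather_ids = ids)
  expect_equal(nrow(scan), 960)
  set.seed(1)
  res <- data.frame(weather_id = scan$weather_id, doy = scan$doy,
                    fresh_yield = runif(nrow(scan), 1, 8))
  res$group <- period_group(res$weather_id)
  expect_setequal(unique(res$group), c("2020-2050s", "2060-2090s"))
  expect_equal(period_group("1980_3"), "1980-2010s")
  # pooling 10 stochastic seeds over 5 decade windows -> 50-sample points
  w5 <- seq(2040, 2080, 10)
  ids5 <- as.vector(outer(w5, 1:10, function(w, r) sprintf("%d_%d", w, r)))
  res5 <- data.frame(weather_id = ids5,
                     doy = rep(240L, 50),
                     fresh_yield = runif(50, 1, 8),
                     group = "future")
  res5 <- rbind(res5, within(res5, doy <- 250L))
  opt5 <- optimal_planting(res5)
  expect_true(all(opt5$curve$n == 50))
})

test_that("season runs are deterministic and error on weather gaps", {
  w <- subtropical_weather()
  r1 <- run_season(w, base_config())
  r2 <- run_season(w, base_config())
  expect_identical(r1, r2)
  w_gap <- w[-7000, ]   # an hour inside the planting-harvest window
  expect_error(run_season(w_gap, base_config()), "weather gap: no record for")
  expect_error(run_season(w, garlic_config()), "planting_date")
})

test_that("benign and harsh climates give the expected season outcomes", {
  rs <- subtropical_run()
  expect_gt(rs$bulb_dry, 0)
  expect_gt(rs$final_pd, 0.999 * garlic_config()$coldstress$pd_0)
  expect_true(all(c("emergence", "scape_appearance", "scape_removal",
                    "harvest") %in% rs$events$event))
  rc <- continental_run()
  expect_lt(rc$fresh_yield, 0.2)       # cold-mortality collapse
  expect_lt(rc$final_pd, 1)
})

test_that("a small scan runs end to end and summarizes per replicate", {
  wl <- list("1" = subtropical_weather(1), "2" = subtropical_weather(2))
  scan <- build_scan(c(260, 300), names(wl))
  out <- cached("scan_small", run_scan(scan, wl, base_config()))
  expect_equal(nrow(out), 4)
  expect_true(all(out$fresh_yield >= 0))
  opt <- optimal_planting(out)
  expect_equal(nrow(opt$per_replicate), 2)
  expect_equal(nrow(opt$curve), 2)
  expect_true(all(opt$curve$n == 2))
})

test_that("weather ensembles are reproducible and named by window and rep", {
  ens <- weather_ensemble("subtropical", windows = 2001, n_reps = 2,
                          seed = 9, years = 1)
  expect_length(ens, 2)
  expect_named(ens, c("2001_1", "2001_2"))
  ens2 <- weather_ensemble("subtropical", windows = 2001, n_reps = 2,
                           seed = 9, years = 1)
  expect_identical(ens, ens2)
  tr <- co2_trajectory(c(`2000` = 400, `2100` = 800))
  ens3 <- weather_ensemble("subtropical", windows = 2050, n_reps = 1,
                           seed = 1, years = 1, co2 = tr)
  expect_equal(ens3[["2050_1"]]$CO2[1], 600)
})

test_that("doy conversion respects leap years", {
  expect_equal(doy_to_date(2001, 240), as.Date("2001-08-28"))
  expect_equal(doy_to_date(2004, 240), as.Date("2004-08-27"))
  expect_equal(doy_to_date(2001, 1), as.Date("2001-01-01"))
})
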