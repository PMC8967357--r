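p_default <- garlic_config()$phenology

test_that("storage sigmoid hits its midpoint, asymptote and zero-storage value", {
  expect_equal(initial_ltar(p_default$sd_m, p_default),
               p_default$ltar_max_a / 2)
  expect_equal(initial_ltar(1e4, p_default), p_default$ltar_max_a,
               tolerance = 1e-8)
  # direct evaluation of the sigmoid at SD = 0
  expect_equal(initial_ltar(0, p_default),
               0.4421 / (1 + exp(0.0256 * 117.7523)), tolerance = 1e-12)
  expect_equal(initial_ltar(0, p_default), 0.0207, tolerance = 1e-3)
})

test_that("storage sigmoid is strictly increasing and symmetric about SD_m", {
  sd_grid <- seq(0, 400, by = 2)
  r <- initial_ltar(sd_grid, p_default)
  expect_true(all(diff(r) > 0))
  expect_true(all(r > 0 & r < p_default$ltar_max_a))
  for (x in c(10, 50, 117)) {
    expect_equal(initial_ltar(p_default$sd_m + x, p_default) +
                   initial_ltar(p_default$sd_m - x, p_default),
                 p_default$ltar_max_a, tolerance = 1e-12)
  }
})

test_that("LTAR_max converges linearly to half the asymptote and clamps past N_g", {
  r0 <- 0.0207
  expect_equal(converge_ltar(r0, 0, p_default), r0)
  expect_equal(converge_ltar(r0, p_default$n_g, p_default),
               p_default$ltar_max_a / 2)
  expect_equal(converge_ltar(0.0207, 5, p_default),
               0.0207 + (0.22105 - 0.0207) / 2, tolerance = 1e-12)
  # clamped at r1 once rank passes the generic leaf number
  expect_equal(converge_ltar(r0, 15, p_default),
               converge_ltar(r0, p_default$n_g, p_default))
  # bounded between r0 and r1 for any rank
  k <- 0:20
  v <- converge_ltar(r0, k, p_default)
  expect_true(all(v >= min(r0, 0.22105) - 1e-12 &
                    v <= max(r0, 0.22105) + 1e-12))
  expect_true(all(diff(v) >= 0))
})

test_that("leaf appearance accumulates at rate x thermal response", {
  # constant rate 0.5/d at the thermal optimum: first leaf after 1/rate = 2 d
  st <- list(r0 = 0.5, r1 = 0.5, k = 0, ltar_max = 0.5, acc = 0)
  p <- modifyList(p_default, list(ltar_max_a = 1.0))  # r1 = 0.5: rate stays fixed
  res <- step_leaf_appearance(st, p$t_opt, 1.9, p)    # < 2 d: not yet
  expect_equal(res$appearances, 0)
  res <- step_leaf_appearance(res$state, p$t_opt, 0.1, p)  # reaches 2 d
  expect_equal(res$appearances, 1)
  expect_equal(res$state$k, 1)
  # freezing temperatures: response factor 0, no appearance ever
  st <- list(r0 = 0.5, r1 = 0.5, k = 0, ltar_max = 0.5, acc = 0)
  for (day in 1:30) {
    res <- step_leaf_appearance(st, rep(-2, 24), 1 / 24, p)
    st <- res$state
    expect_equal(res$appearances, 0)
  }
  expect_equal(st$k, 0)
})

test_that("phyllochrons lengthen monotonically when r0 exceeds r1", {
  p <- modifyList(p_default, list(max_leaves = 12))
  st <- init_phyllochron(1e4, p)        # very long storage: r0 -> asymptote > r1
  expect_gt(st$r0, p$ltar_max_a / 2)
  appear_hour <- c()
  for (h in 1:3000) {    # hour-by-hour so intervals resolve sub-daily
    res <- step_leaf_appearance(st, p$t_opt, 1 / 24, p)
    st <- res$state
    if (res$appearances > 0) appear_hour <- c(appear_hour, h)
    if (length(appear_hour) >= 10) break
  }
  intervals <- diff(appear_hour)
  expect_true(all(diff(intervals) >= 0))
  # converged interval approaches 1/r1 (in days) at the optimum
  expect_equal(intervals[length(intervals)] / 24, 1 / (p$ltar_max_a / 2),
               tolerance = 0.3)
})

test_that("stage transitions move strictly forward", {
  expect_equal(advance_stage("seed", "vegetative"), "vegetative")
  expect_equal(advance_stage("R2", "R3"), "R3")
  expect_error(advance_stage("R2", "vegetative"), "forward")
  expect_error(advance_stage("R1", "R1"), "forward")
  expect_identical(dev_stages(),
                   c("seed", "vegetative", "R1", "R2", "R3", "death"))
})

test_that("season stage sequence is a forward subsequence and scape timing follows the phyllochron", {
  # constant optimal temperature, storage at SD_m so the rate stays at r1
  pd <- as.Date("2001-10-26")  # SD = 118 days ~ SD_m
  w <- constant_weather(22, days = 210, start = "2001-10-26")
  cfg <- garlic_config(simulation = list(planting_date = pd,
                                         harvest_date = "05-15"),
                       phenology = list(repro_onset_gdd = 300))
  res <- run_season(w, cfg)
  ev <- res$events
  stages <- unique(res$daily$stage)
  expect_true(all(diff(match(stages, dev_stages())) > 0))
  t_init <- ev$date[ev$event == "scape_initiation"]
  t_app <- ev$date[ev$event == "scape_appearance"]
  expect_length(t_init, 1); expect_length(t_app, 1)
  # three phyllochrons at the converged rate (thermal factor 1 at 22 degC)
  expected <- 3 / (garlic_config()$phenology$ltar_max_a / 2)
  expect_equal(as.numeric(t_app - t_init), expected, tolerance = 0.15)
  # immediate removal policy: R2 lasts under a day, R3 entered same day
  t_rm <- ev$date[ev$event == "scape_removal"]
  expect_equal(as.numeric(t_rm - t_app), 0)
  expect_true("R3" %in% res$daily$stage)
})

test_that("without removal R3 is never entered", {
  w <- constant_weather(22, days = 210, start = "2001-10-26")
  cfg <- garlic_config(simulation = list(planting_date = as.Date("2001-10-26"),
                                         scape_removal = "none"),
                       phenology = list(repro_onset_gdd = 300))
  res <- run_season(w, cfg)
  expect_false("R3" %in% res$daily$stage)
  expect_true("R2" %in% res$daily$stage)
  expect_equal(res$scape_yield, 0)
})

test_that("storage duration is measured from the June 30 seed harvest", {
  expect_equal(storage_duration(as.Date("2001-10-01")), 93)
  expect_equal(storage_duration(as.Date("2002-01-15")), 199)
  expect_equal(storage_duration(as.Date("2001-06-30")), 0)
})
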