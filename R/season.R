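#' @title Whole-season simulation
#' @name season
#' @description Integrates weather, phenology, cold stress, carbon
#'   assimilation, allocation and morphology over a planting-to-harvest
#'   season at an hourly/daily hybrid timestep: assimilation and leaf
#'   appearance integrate hourly weather; cold stress, elongation,
#'   senescence and allocation update once per day (cold stress from
#'   the daily minimum temperature).
NULL

resolve_date <- function(x, ref_date = NULL) {
  if (inherits(x, "Date")) return(x)
  if (grepl("^\\d{4}-\\d{2}-\\d{2}$", x)) return(as.Date(x))
  if (grepl("^\\d{2}-\\d{2}$", x)) {
    stopifnot(!is.null(ref_date))
    yr <- as.integer(strftime(ref_date, "%Y"))
    d <- as.Date(paste0(yr, "-", x))
    if (d <= ref_date) d <- as.Date(paste0(yr + 1, "-", x))
    return(d)
  }
  stop("unparseable date: ", x)
}

#' Run a single growing season
#'
#' Simulates one plant (scaled by plant density) from planting to the
#' fixed harvest date. Deterministic given the weather and
#' configuration: the same inputs reproduce the result bit for bit.
#'
#' @param weather hourly `weather_series` covering planting 00:00
#'   through harvest 23:00 with no gaps (a gap raises an error naming
#'   the missing interval).
#' @param config a [garlic_config()]; `config$simulation$planting_date`
#'   must be set (Date or "YYYY-MM-DD"). `config$simulation$co2` may be
#'   `NULL` (use the weather file's CO2 column), a scalar, or a
#'   [co2_trajectory()] evaluated at each simulation day.
#' @return A `season_result` list: `daily` (per-day state data.frame:
#'   date, stage, leaf_count, green_area, lai, organ masses, PD, cold
#'   state, assimilate), `events` (data.frame of dated phenology
#'   events), `bulb_dry` (g plant^-1), `fresh_yield` (kg m^-2 at the
#'   configured bulb moisture), `scape_yield` (g plant^-1 removed),
#'   `final_pd` (plants m^-2), and `carbon` (season totals for the
#'   balance: assimilate, unmet respiration, maintenance, structural
#'   growth, initial/final pool).
#' @examples
#' \donttest{
#' w <- synthesize_weather("subtropical", years = 2, seed = 1)
#' cfg <- garlic_config(simulation = list(planting_date = "2001-10-01"))
#' res <- run_season(w, cfg)
#' res$fresh_yield
#' }
#' @export
run_season <- function(weather, config) {
  stopifnot(inherits(config, "garlic_config"))
  if (weather_cadence(weather) != "hourly")
    stop("run_season needs hourly weather; downscale daily input first")
  sim <- config$simulation
  if (is.null(sim$planting_date)) stop("config$simulation$planting_date is not set")
  planting <- as.Date(sim$planting_date)
  harvest <- resolve_date(sim$harvest_date, planting)
  if (harvest <= planting) stop("harvest must follow planting")

  t0 <- as.POSIXct(paste(planting, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(harvest, "23:00:00"), tz = "UTC")
  need <- seq(t0, t1, by = 3600)
  idx <- match(need, weather$timestamp)
  if (anyNA(idx)) {
    miss <- need[which(is.na(idx))[1]]
    stop("weather gap: no record for ", format(miss, "%Y-%m-%d %H:%M"))
  }
  wx <- weather[idx, ]
  n_days <- length(need) / 24
  dates <- seq(planting, harvest, by = "day")
  Tm <- matrix(wx$T_air, nrow = 24)
  Sm <- matrix(wx$solar, nrow = 24)
  Hm <- matrix(wx$RH, nrow = 24)
  Wm <- matrix(wx$wind, nrow = 24)
  Cm <- matrix(wx$CO2, nrow = 24)
  if (!is.null(sim$co2)) {
    if (inherits(sim$co2, "co2_trajectory")) {
      Cm <- matrix(rep(co2_at(sim$co2, dates), each = 24), nrow = 24)
    } else {
      Cm[] <- sim$co2
    }
  }

  ph <- config$phenology; cs <- config$coldstress
  mo <- config$morphology; ge <- config$gas_exchange
  al <- config$allocation
  validate_partition_table(al$partition_table)

  sd_days <- storage_duration(planting, ph$seed_harvest_date)
  phyll <- init_phyllochron(sd_days, ph)
  stage <- "seed"
  biomass <- stats::setNames(numeric(5), organ_names())
  pool <- al$initial_pool
  pd <- cs$pd_0
  d_cold <- 0; e_prev <- 1
  gdd <- 0; scape_acc <- 0
  scape_yield <- 0
  lai_now <- 0
  n_leaf_max <- ph$max_leaves
  lf_len <- numeric(0); lf_pot <- numeric(0); lf_age <- numeric(0)

  events <- list()
  log_event <- function(date, what) events[[length(events) + 1L]] <<-
    data.frame(date = date, event = what, stringsAsFactors = FALSE)

  tot_assim <- 0; tot_unmet <- 0; tot_maint <- 0; tot_growth <- 0

  daily <- data.frame(
    date = dates, stage = character(n_days), leaf_count = integer(n_days),
    green_area = numeric(n_days), lai = numeric(n_days),
    root = numeric(n_days), leaf = numeric(n_days),
    sheath = numeric(n_days), scape = numeric(n_days),
    bulb = numeric(n_days), pd = numeric(n_days),
    cold_days = numeric(n_days), injury_effect = numeric(n_days),
    assimilate = numeric(n_days), stringsAsFactors = FALSE
  )

  scape_removal_date <- if (startsWith(sim$scape_removal, "date:"))
    resolve_date(sub("^date:", "", sim$scape_removal), planting) else NULL

  for (day in seq_len(n_days)) {
    th <- Tm[, day]; t_min <- min(th); t_mean <- mean(th)

    # --- cold stress (daily minimum temperature) ---
    d_cold <- update_cold_days(d_cold, t_min, cs)
    if (d_cold == 0) {
      e_t <- 1; e_prev <- 1
    } else {
      e_t <- injury_effect(apparent_injury(t_min, cs), d_cold, e_prev)
      e_prev <- e_t
    }
    # a damage event is a frost day (daily minimum below the injury
    # threshold); without frost the density trajectory is untouched
    if (t_min < cs$t_c_i) pd <- update_density(pd, t_min, cs)

    # --- canopy assimilation on yesterday's LAI ---
    assim <- if (lai_now > 0) {
      env <- canopy_env(Sm[, day], th, Hm[, day], Wm[, day], Cm[, day],
                        lai_now, pd)
      if (identical(sim$carbon_source, "rue"))
        sum(rue_assimilation(env, sim$rue, ge$k))
      else
        sum(canopy_assimilation(env, ge))
    } else 0

    # --- leaf appearance (hourly accumulation) ---
    res <- step_leaf_appearance(phyll, th, 1 / 24, ph)
    if (res$appearances > 0) {
      for (r in seq_len(res$appearances)) {
        rank <- length(lf_len) + 1L
        lf_len <- c(lf_len, 0)
        lf_pot <- c(lf_pot, leaf_potential_length(rank, mo, n_leaf_max))
        lf_age <- c(lf_age, 0)
      }
      if (stage == "seed") {
        stage <- advance_stage(stage, "vegetative")
        log_event(dates[day], "emergence")
      }
      log_event(dates[day], sprintf("leaf_appearance_%d", length(lf_len)))
    }
    phyll <- res$state

    # --- thermal time and stage transitions ---
    if (stage != "seed") gdd <- gdd + max(t_mean - ph$gdd_base, 0)
    if (stage == "vegetative" && gdd >= ph$repro_onset_gdd) {
      stage <- advance_stage(stage, "R1")
      scape_acc <- 0
      log_event(dates[day], "scape_initiation")
    }
    if (stage == "R1") {
      f_day <- mean(thermal_response(th, ph$t_base, ph$t_opt, ph$t_ceil))
      scape_acc <- scape_acc + phyll$ltar_max * f_day
      if (scape_acc >= ph$scape_phyllochrons) {
        stage <- advance_stage(stage, "R2")
        log_event(dates[day], "scape_appearance")
      }
    }
    if (stage == "R2") {
      do_remove <- identical(sim$scape_removal, "immediate") ||
        (!is.null(scape_removal_date) && dates[day] >= scape_removal_date)
      if (do_remove) {
        rs <- remove_scape(biomass, stage, al$scape_visible_fraction)
        biomass <- rs$biomass
        scape_yield <- scape_yield + rs$removed
        stage <- rs$stage
        log_event(dates[day], "scape_removal")
      }
    }

    # --- leaf elongation (injury-scaled) and senescence ---
    green_area <- 0
    if (length(lf_len)) {
      ler <- apply_injury(potential_ler(t_mean, mo), e_t)
      lf_len <- grow_leaf(lf_len, lf_pot, ler)
      lf_age <- lf_age + thermal_response(t_mean, mo$t_base, mo$t_opt, mo$t_ceil)
      gf <- green_fraction(lf_age, mo)
      green_area <- sum(leaf_area(lf_len, lf_pot, mo) * gf)
      if (stage != "death" && length(lf_len) >= n_leaf_max &&
          green_area <= 0) {
        stage <- "death"
        log_event(dates[day], "death")
      }
    }

    # --- carbon pool and partitioning ---
    sp <- step_pool(pool, assim, biomass, t_mean, al)
    inc <- partition(sp$allocation, stage, al$partition_table)
    biomass <- biomass + inc
    pool <- sp$pool
    tot_assim <- tot_assim + assim
    tot_unmet <- tot_unmet + sp$unmet_respiration
    tot_maint <- tot_maint + sp$maintenance_paid
    tot_growth <- tot_growth + sum(inc)

    lai_now <- lai(green_area, pd)

    daily$stage[day] <- stage
    daily$leaf_count[day] <- length(lf_len)
    daily$green_area[day] <- green_area
    daily$lai[day] <- lai_now
    daily[day, organ_names()] <- as.list(biomass)
    daily$pd[day] <- pd
    daily$cold_days[day] <- d_cold
    daily$injury_effect[day] <- e_t
    daily$assimilate[day] <- assim
  }
  log_event(harvest, "harvest")

  structure(list(
    daily = daily,
    events = do.call(rbind, events),
    bulb_dry = unname(biomass[["bulb"]]),
    fresh_yield = fresh_yield(biomass[["bulb"]], pd, sim$bulb_moisture),
    scape_yield = scape_yield,
    final_pd = pd,
    planting_date = planting, harvest_date = harvest,
    carbon = list(assimilate = tot_assim, unmet_respiration = tot_unmet,
                  maintenance = tot_maint, growth = tot_growth,
                  y_g = al$y_g, initial_pool = al$initial_pool,
                  final_pool = pool)
  ), class = "season_result")
}

#' @export
print.season_result <- function(x, ...) {
  cat("<season_result> ", format(x$planting_date), " -> ",
      format(x$harvest_date), "\n", sep = "")
  cat(sprintf("  bulb dry mass : %.2f g plant^-1\n", x$bulb_dry))
  cat(sprintf("  fresh yield   : %.3f kg m^-2\n", x$fresh_yield))
  cat(sprintf("  scape yield   : %.2f g plant^-1\n", x$scape_yield))
  cat(sprintf("  final density : %.2f plants m^-2\n", x$final_pd))
  cat(sprintf("  events        : %s\n",
              paste(x$events$event, collapse = ", ")))
  invisible(x)
}

#' Fresh bulb yield per ground area
#'
#' Converts bulb dry mass to fresh yield at the configured bulb
#' moisture content (default 85 %):
#' `bulb_dry / (1 - moisture) * pd / 1000` (kg m^-2).
#'
#' @param bulb_dry bulb dry mass (g plant^-1).
#' @param pd plant density (plants m^-2).
#' @param moisture bulb moisture fraction in \[0, 1).
#' @return fresh yield (kg m^-2).
#' @examples
#' fresh_yield(3, 50, 0.85)  # 1 kg m^-2
#' @export
fresh_yield <- function(bulb_dry, pd, moisture = 0.85) {
  if (any(moisture >= 1) || any(moisture < 0))
    stop("moisture must lie in [0, 1)")
  bulb_dry / (1 - moisture) * pd / 1000
}
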