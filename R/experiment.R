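#' @title Planting-date x weather-ensemble experiments
#' @name experiment
#' @description Factorial machinery for scanning planting dates across
#'   stochastic weather ensembles and climate scenarios: the default
#'   design adjusts planting from DOY 240 to 350 in 10-day steps (12
#'   dates) against each weather dataset, giving 120 runs for a
#'   single-window 10-replicate ensemble and 960 runs for an
#'   8-window x 10-replicate scenario ensemble. Yields are extracted at
#'   a fixed harvest date and optimal planting dates located per
#'   replicate.
NULL

#' Default planting-date grid
#'
#' @return integer DOYs 240, 250, ..., 350 (12 values).
#' @export
default_planting_doys <- function() seq(240L, 350L, by = 10L)

#' Build a planting-date x weather scan
#'
#' Cartesian product of planting DOYs and weather dataset identifiers;
#' one row per simulation run.
#'
#' @param planting_doys integer vector of planting days of year
#'   (default [default_planting_doys()]).
#' @param weather_ids vector of dataset labels (e.g. one per stochastic
#'   seed, or per decade-window x seed combination).
#' @return data.frame with columns `doy` and `weather_id`;
#'   `nrow = length(planting_doys) * length(weather_ids)`.
#' @examples
#' nrow(build_scan(weather_ids = 1:10))   # 120
#' nrow(build_scan(weather_ids = 1:80))   # 960
#' @export
build_scan <- function(planting_doys = default_planting_doys(),
                       weather_ids) {
  stopifnot(length(planting_doys) >= 1, length(weather_ids) >= 1)
  g <- expand.grid(doy = as.integer(planting_doys),
                   weather_id = weather_ids,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[order(g$weather_id, g$doy), , drop = FALSE]
}

#' Convert a day of year to a date
#'
#' @param year calendar year.
#' @param doy day of year (1-366).
#' @return a `Date`.
#' @export
doy_to_date <- function(year, doy) {
  as.Date(doy - 1, origin = as.Date(paste0(year, "-01-01")))
}

#' Run a planting-date scan
#'
#' Executes [run_season()] for every row of a scan design. Planting
#' falls in the first calendar year of each weather dataset and harvest
#' on the configured date (default May 15) of the following year, so
#' each dataset must span at least two calendar years of hourly
#' records.
#'
#' @param scan data.frame from [build_scan()].
#' @param weather_list named list (or list indexed by `weather_id`) of
#'   hourly `weather_series`.
#' @param config base [garlic_config()]; the planting date is
#'   overridden per run.
#' @return data.frame with one row per run: `weather_id`, `doy`,
#'   `planting_date`, `fresh_yield` (kg m^-2), `bulb_dry` (g plant^-1),
#'   `scape_yield`, `final_pd`.
#' @export
run_scan <- function(scan, weather_list, config = garlic_config()) {
  out <- vector("list", nrow(scan))
  for (i in seq_len(nrow(scan))) {
    wid <- scan$weather_id[i]
    w <- weather_list[[as.character(wid)]]
    if (is.null(w)) w <- weather_list[[wid]]
    if (is.null(w)) stop("no weather dataset for id ", wid)
    yr <- as.integer(strftime(w$timestamp[1], "%Y"))
    pdate <- doy_to_date(yr, scan$doy[i])
    cfg <- config
    cfg$simulation$planting_date <- pdate
    res <- run_season(w, cfg)
    out[[i]] <- data.frame(
      weather_id = wid, doy = scan$doy[i], planting_date = pdate,
      fresh_yield = res$fresh_yield, bulb_dry = res$bulb_dry,
      scape_yield = res$scape_yield, final_pd = res$final_pd,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Optimal planting dates and yield-vs-DOY curves
#'
#' For each replicate (weather dataset, i.e. one stochastic year) the
#' optimal planting date is the DOY with maximum fresh yield, ties
#' broken toward the earlier date. Yield curves report mean +/- SD per
#' DOY across replicates; when a `group` column is supplied (e.g. a
#' period label pooling decade windows), curves and optima are
#' summarized per group, so a future-scenario data point pooling 10
#' stochastic seeds over 5 decade windows carries 50 samples.
#'
#' @param results data.frame from [run_scan()] (needs `weather_id`,
#'   `doy`, `fresh_yield`; optionally `group`).
#' @return list with `per_replicate` (weather_id \[, group\], opt_doy,
#'   max_yield), `curve` (\[group,\] doy, mean_yield, sd_yield, n), and
#'   `optimum` (\[group,\] mean/sd of the per-replicate optimal DOY and
#'   n).
#' @export
optimal_planting <- function(results) {
  stopifnot(all(c("weather_id", "doy", "fresh_yield") %in% names(results)))
  has_group <- "group" %in% names(results)
  results <- results[order(results$weather_id, results$doy), ]

  rep_keys <- if (has_group)
    interaction(results$group, results$weather_id, drop = TRUE)
  else factor(results$weather_id, levels = unique(results$weather_id))
  per_rep <- do.call(rbind, lapply(split(results, rep_keys), function(d) {
    i <- which.max(d$fresh_yield)   # first max = earliest DOY on sorted data
    out <- data.frame(weather_id = d$weather_id[1], opt_doy = d$doy[i],
                      max_yield = d$fresh_yield[i], stringsAsFactors = FALSE)
    if (has_group) out$group <- d$group[1]
    out
  }))
  rownames(per_rep) <- NULL

  curve_keys <- if (has_group) interaction(results$group, results$doy, drop = TRUE)
  else factor(results$doy)
  curve <- do.call(rbind, lapply(split(results, curve_keys), function(d) {
    out <- data.frame(doy = d$doy[1], mean_yield = mean(d$fresh_yield),
                      sd_yield = stats::sd(d$fresh_yield), n = nrow(d))
    if (has_group) out <- cbind(group = d$group[1], out)
    out
  }))
  curve <- if (has_group) curve[order(curve$group, curve$doy), ]
  else curve[order(curve$doy), ]
  rownames(curve) <- NULL

  opt_keys <- if (has_group) factor(per_rep$group) else factor("all")
  optimum <- do.call(rbind, lapply(split(per_rep, opt_keys), function(d) {
    data.frame(group = if (has_group) d$group[1] else "all",
               mean_opt_doy = mean(d$opt_doy),
               sd_opt_doy = stats::sd(d$opt_doy),
               mean_max_yield = mean(d$max_yield),
               sd_max_yield = stats::sd(d$max_yield),
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(optimum) <- NULL

  list(per_replicate = per_rep, curve = curve, optimum = optimum)
}

#' Generate a weather ensemble
#'
#' Convenience wrapper producing `n_reps` stochastic two-year (or
#' longer) hourly datasets per decade window from
#' [synthesize_weather()], mirroring an 8-window x 10-replicate
#' scenario ensemble (80 datasets) or a single-window current-climate
#' ensemble (10 datasets).
#'
#' @param profile climate profile passed to [synthesize_weather()].
#' @param windows vector of window start years (e.g. `seq(2020, 2090,
#'   10)` for eight decade windows, or a single year for the current
#'   climate).
#' @param n_reps stochastic repetitions per window.
#' @param seed base seed; each dataset uses `seed + index`.
#' @param years calendar years per dataset (>= 2 so a fall planting can
#'   reach a May harvest).
#' @param co2 scalar CO2 or a [co2_trajectory()] evaluated at each
#'   window start year.
#' @param severity seasonal-amplitude multiplier.
#' @return named list of `weather_series`; names are
#'   `"<window>_<rep>"`.
#' @export
weather_ensemble <- function(profile, windows, n_reps = 10, seed = 1,
                             years = 2, co2 = 400, severity = 1) {
  out <- list()
  i <- 0L
  for (wnd in windows) {
    co2_w <- if (inherits(co2, "co2_trajectory")) co2_at(co2, wnd) else co2
    for (r in seq_len(n_reps)) {
      i <- i + 1L
      out[[sprintf("%d_%d", wnd, r)]] <-
        synthesize_weather(profile, years = years, seed = seed + i,
                           severity = severity, start_year = wnd,
                           co2 = co2_w)
    }
  }
  out
}

#' Group decade windows into reporting periods
#'
#' Maps the window start year encoded in ensemble dataset names
#' (`"<window>_<rep>"`) to the three reporting periods used for yield
#' comparison: 1980-2010s (historical), 2020-2050s, and 2060-2090s.
#'
#' @param weather_id character vector of dataset names.
#' @return character vector of period labels.
#' @export
period_group <- function(weather_id) {
  wnd <- as.integer(sub("_.*$", "", weather_id))
  ifelse(wnd < 2020, "1980-2010s",
         ifelse(wnd < 2060, "2020-2050s", "2060-2090s"))
}
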