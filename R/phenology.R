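#' @title Dynamic phyllochron and developmental stages
#' @name phenology
#' @description Leaf appearance is driven by accumulating the leaf tip
#'   appearance rate (LTAR, d^-1). The maximal rate under optimal
#'   temperature (`LTAR_max`) is initialized from seed-bulb storage
#'   duration through a sigmoid and then, after each leaf appearance,
#'   moves linearly toward half of the asymptote, reaching it when leaf
#'   rank equals the generic leaf number. A scape appears three
#'   phyllochrons after the onset of the reproductive stage.
NULL

#' Storage-conditioned initial leaf tip appearance rate
#'
#' Sigmoid of storage duration:
#' \deqn{r_0 = \frac{LTAR_{max,a}}{1 + e^{-\alpha (SD - SD_m)}}}
#' where `SD_m` is the storage duration giving half the asymptote and
#' `alpha` the steepness. Storage temperature is accepted in the
#' configuration for forward compatibility but does not enter this
#' relation.
#'
#' @param sd storage duration between seed harvest and planting (days,
#'   >= 0); vectorized.
#' @param p phenology section of [garlic_config()] (needs `ltar_max_a`,
#'   `sd_m`, `alpha`).
#' @return initial rate r0 (d^-1), strictly increasing in `sd`,
#'   bounded in (0, `ltar_max_a`).
#' @examples
#' p <- garlic_config()$phenology
#' initial_ltar(p$sd_m, p)    # exactly half the asymptote
#' @export
initial_ltar <- function(sd, p) {
  stopifnot(all(sd >= 0), p$ltar_max_a > 0)
  p$ltar_max_a / (1 + exp(-p$alpha * (sd - p$sd_m)))
}

#' Converged maximal leaf tip appearance rate at a given leaf rank
#'
#' Linear convergence from the storage-conditioned initial rate `r0`
#' toward `r1 = LTAR_max_a / 2`:
#' \deqn{LTAR_{max}(k) = r_0 + (r_1 - r_0)\,\min(k, N_g)/N_g}
#' Convergence is complete once leaf rank `k` reaches the generic leaf
#' number `N_g`; beyond that the rate stays at `r1`.
#'
#' @param r0 initial rate (d^-1) from [initial_ltar()].
#' @param k current leaf rank (count, >= 0); vectorized.
#' @param p phenology config section (`ltar_max_a`, `n_g`).
#' @return LTAR_max (d^-1), between `min(r0, r1)` and `max(r0, r1)`.
#' @export
converge_ltar <- function(r0, k, p) {
  stopifnot(all(k >= 0), p$n_g >= 1)
  r1 <- p$ltar_max_a / 2
  r0 + (r1 - r0) * pmin(k, p$n_g) / p$n_g
}

#' Storage duration from harvest and planting dates
#'
#' Days between the assumed seed-bulb harvest date (default June 30 of
#' the planting year, or the previous year when planting falls before
#' it) and planting.
#'
#' @param planting_date a `Date`.
#' @param seed_harvest_date `"MM-DD"` string.
#' @return storage duration in days (>= 0).
#' @export
storage_duration <- function(planting_date, seed_harvest_date = "06-30") {
  planting_date <- as.Date(planting_date)
  yr <- as.integer(strftime(planting_date, "%Y"))
  harvest <- as.Date(paste0(yr, "-", seed_harvest_date))
  harvest[harvest > planting_date] <-
    as.Date(paste0(yr - 1, "-", seed_harvest_date))[harvest > planting_date]
  as.numeric(planting_date - harvest)
}

# --- leaf appearance stepping ----------------------------------------------

#' Create the phyllochron state at planting
#'
#' @param sd storage duration (days).
#' @param p phenology config section.
#' @return list with fields `r0`, `r1`, `k` (leaf rank, starts 0),
#'   `ltar_max` (current maximal rate) and `acc` (progress toward the
#'   next appearance, in leaves).
#' @export
init_phyllochron <- function(sd, p) {
  r0 <- initial_ltar(sd, p)
  list(r0 = r0, r1 = p$ltar_max_a / 2, k = 0,
       ltar_max = converge_ltar(r0, 0, p), acc = 0)
}

#' Advance leaf appearance over one or more timesteps
#'
#' Integrates `LTAR_max x f(T)` where `f` is the beta thermal response
#' of the phenology config. Each time the accumulator crosses 1 a leaf
#' appears: rank `k` increments, the accumulator drops by 1, and
#' `LTAR_max` is re-converged via [converge_ltar()]. Leaf appearance
#' stops at `max_leaves` (total initiable leaves) but the accumulator
#' keeps integrating so phyllochron-based counters (scape timing)
#' remain driven.
#'
#' @param state phyllochron state from [init_phyllochron()].
#' @param t_air air temperatures (degC), one per timestep; vector.
#' @param dt_days timestep length in days (e.g. 1/24 for hourly).
#' @param p phenology config section.
#' @return list `state` (updated) and `appearances` (number of new
#'   leaves this call).
#' @export
step_leaf_appearance <- function(state, t_air, dt_days, p) {
  stopifnot(dt_days > 0)
  f <- thermal_response(t_air, p$t_base, p$t_opt, p$t_ceil)
  appeared <- 0L
  max_leaves <- if (is.null(p$max_leaves)) Inf else p$max_leaves
  for (ft in f) {
    state$acc <- state$acc + state$ltar_max * ft * dt_days
    while (state$acc >= 1) {
      state$acc <- state$acc - 1
      if (state$k < max_leaves) {
        state$k <- state$k + 1L
        appeared <- appeared + 1L
        state$ltar_max <- converge_ltar(state$r0, state$k, p)
      }
    }
  }
  list(state = state, appearances = appeared)
}

# --- developmental stages ---------------------------------------------------

#' Developmental stage codes
#'
#' Stages progress strictly forward through `seed` (planting to
#' emergence), `vegetative`, `R1` (scape initiation to appearance),
#' `R2` (scape appearance to removal), `R3` (after removal; only
#' entered if the scape is removed), and `death`.
#'
#' @return character vector of the six stage names in order.
#' @export
dev_stages <- function() stage_names()

stage_index <- function(stage) match(stage, stage_names())

#' Advance the developmental stage
#'
#' Encodes the forward-only transition rules: `seed -> vegetative` at
#' emergence (first leaf appearance), `vegetative -> R1` when thermal
#' time after emergence (growing degree days above `gdd_base`) reaches
#' `repro_onset_gdd`, `R1 -> R2` when the phyllochron counter has
#' accumulated `scape_phyllochrons` further leaf-appearance equivalents
#' since onset, `R2 -> R3` on scape removal, and any stage to `death`.
#'
#' @param stage current stage name.
#' @param to proposed next stage name.
#' @return `to`, invisibly erroring if the transition moves backward.
#' @export
advance_stage <- function(stage, to) {
  i <- stage_index(stage); j <- stage_index(to)
  if (is.na(i) || is.na(j)) stop("unknown stage")
  if (j <= i) stop("stage transitions only move forward (", stage,
                   " -> ", to, ")")
  to
}
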