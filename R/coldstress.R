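#' @title Cold injury and cold damage
#' @name coldstress
#' @description Two responses to winter cold: recoverable *cold injury*
#'   scales leaf elongation down through an effect E(t) in \[0,1\]
#'   derived from the apparent injury C at the current temperature and
#'   the running count of cold days D; irreversible *cold damage* kills
#'   plants through a logistic mortality in temperature, permanently
#'   reducing plant density. Both are evaluated once per day from the
#'   daily minimum temperature.
NULL

#' Update the cumulative cold-day counter
#'
#' The daily indicator is +1 when the day's temperature is below the
#' critical injury temperature and -1 otherwise; the running sum is
#' floored at zero, so warm days erode the counter until the episode
#' resets.
#'
#' @param d_days current counter D (days, >= 0).
#' @param t_daily daily (minimum) air temperature (degC).
#' @param p coldstress config section (`t_c_i`).
#' @return updated D (>= 0).
#' @examples
#' p <- garlic_config()$coldstress
#' update_cold_days(0, 5, p)   # stays 0
#' update_cold_days(0, -5, p)  # 1
#' @export
update_cold_days <- function(d_days, t_daily, p) {
  stopifnot(d_days >= 0)
  max(d_days + if (t_daily < p$t_c_i) 1 else -1, 0)
}

#' Apparent cold injury at a temperature
#'
#' Logarithmic severity clamped to \[0,1\]:
#' \deqn{C = \max(0, \min(\ln[a (T - T_{c,i}) + b], 1))}
#' With the default parameters (a = -0.1, b = 1.6) C is about 0.47 at
#' 0 degC, rises as temperature falls, and saturates at 1 near -11
#' degC. The natural logarithm is used: it is the reading under which
#' injury saturates before the damage-mortality peak near -20 degC.
#' When the log argument is non-positive (warm temperatures) C clamps
#' to 0.
#'
#' @param t air temperature (degC); vectorized.
#' @param p coldstress config section (`t_c_i`, `cold_a`, `cold_b`).
#' @return C in \[0,1\], non-increasing in `t` for `cold_a < 0`.
#' @export
apparent_injury <- function(t, p) {
  arg <- p$cold_a * (t - p$t_c_i) + p$cold_b
  c_raw <- rep(-Inf, length(arg))
  ok <- arg > 0
  c_raw[ok] <- log(arg[ok])
  pmin(pmax(c_raw, 0), 1)
}

#' Cold injury effect on leaf elongation
#'
#' While a cold episode is in effect (D > 0) the potential effect is
#' \eqn{E = 1 - C^{1/D}}, attenuated so that longer exposure makes
#' recovery harder, and the applied effect never exceeds yesterday's:
#' \eqn{E(t) = \min(E, E(t-1))}. When the counter has reset (D = 0) the
#' effect is 1 (no injury).
#'
#' @param c_apparent apparent injury C in \[0,1\].
#' @param d_days cold-day counter D (>= 0).
#' @param e_prev previously applied effect E(t-1) in \[0,1\].
#' @return E(t) in \[0,1\].
#' @export
injury_effect <- function(c_apparent, d_days, e_prev = 1) {
  stopifnot(c_apparent >= 0, c_apparent <= 1, d_days >= 0,
            e_prev >= 0, e_prev <= 1)
  if (d_days == 0) return(1)
  e_pot <- 1 - c_apparent^(1 / d_days)
  min(e_pot, e_prev)
}

#' Scale potential leaf elongation by cold injury
#'
#' @param ler_p potential leaf elongation rate (cm d^-1, >= 0).
#' @param e_t injury effect in \[0,1\].
#' @return actual LER = E(t) * LER_p (cm d^-1).
#' @export
apply_injury <- function(ler_p, e_t) {
  stopifnot(all(ler_p >= 0), all(e_t >= 0), all(e_t <= 1))
  e_t * ler_p
}

#' Cold-damage mortality
#'
#' Logistic fraction of plants killed by an extreme-cold event:
#' \deqn{M = \frac{e^{-s (T - T_{c,d})}}{1 + e^{-s (T - T_{c,d})}}}
#' M is 0.5 exactly at the critical damage temperature (default -15
#' degC) and, with the default shape factor 0.9, builds up below about
#' -10 degC and saturates near -20 degC.
#'
#' @param t air temperature (degC); vectorized.
#' @param p coldstress config section (`t_c_d`, `cold_s`).
#' @return mortality fraction in (0, 1), strictly decreasing in `t`.
#' @examples
#' p <- garlic_config()$coldstress
#' mortality(-15, p)  # 0.5
#' @export
mortality <- function(t, p) {
  stats::plogis(-p$cold_s * (t - p$t_c_d))
}

#' Apply a cold-damage event to plant density
#'
#' Survival S = 1 - M is applied multiplicatively, once per damage
#' event (one per day, on the daily minimum temperature), so repeated
#' frosts compound: plant density is non-increasing over the season and
#' plants killed by damage never recover.
#'
#' @param pd current plant density (plants m^-2, > 0).
#' @param t_event event temperature (degC), typically the daily minimum.
#' @param p coldstress config section.
#' @return updated density `pd * (1 - M(t_event))`.
#' @export
update_density <- function(pd, t_event, p) {
  stopifnot(pd > 0)
  pd * (1 - mortality(t_event, p))
}
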