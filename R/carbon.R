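#' @title Canopy carbon assimilation
#' @name carbon_assimilation
#' @description Net canopy assimilation per timestep from a C3
#'   photosynthesis model (Farquhar-von Caemmerer-Berry kinetics with
#'   Bernacchi temperature dependencies) coupled to Ball-Berry stomatal
#'   conductance and a linearized leaf energy balance, evaluated over
#'   sunlit and shaded big-leaf fractions partitioned by a canopy
#'   extinction coefficient. A radiation-use-efficiency (RUE) fallback
#'   is provided so downstream behavior can be studied independently of
#'   the gas-exchange parameterization. Garlic-specific kinetic
#'   constants are configurable estimates; the simulator's qualitative
#'   behavior (light and CO2 responses) does not hinge on their exact
#'   values.
NULL

# Bernacchi (2001) Arrhenius scaling from 25 degC
arrhenius <- function(k25, ea, t_leaf) {
  tk <- t_leaf + 273.15
  k25 * exp(ea * (tk - 298.15) / (298.15 * 8.314 * tk))
}

#' Leaf-level coupled gas exchange
#'
#' Solves the intercellular CO2 fixed point of the coupled
#' FvCB/Ball-Berry system by damped iteration (tolerance and iteration
#' cap in the config; defaults 1e-3 umol mol^-1, 100 iterations).
#' Vectorized over its inputs.
#'
#' @param par_leaf absorbed PAR per leaf area (umol m^-2 s^-1).
#' @param t_leaf leaf temperature (degC).
#' @param rh relative humidity (%).
#' @param co2 ambient CO2 (umol mol^-1).
#' @param gb boundary-layer conductance to water vapor (mol m^-2 s^-1).
#' @param p gas_exchange config section.
#' @return list with `a_net` (umol CO2 m^-2 s^-1), `gs`
#'   (mol m^-2 s^-1), `ci` (umol mol^-1), and `iters` used.
#' @export
leaf_gas_exchange <- function(par_leaf, t_leaf, rh, co2, gb, p) {
  n <- max(length(par_leaf), length(t_leaf), length(rh), length(co2),
           length(gb))
  par_leaf <- rep_len(par_leaf, n); t_leaf <- rep_len(t_leaf, n)
  rh <- rep_len(rh, n); co2 <- rep_len(co2, n); gb <- rep_len(gb, n)

  vcmax <- arrhenius(p$vcmax25, 65330, t_leaf)
  jmax  <- arrhenius(p$jmax25, 43540, t_leaf)
  rd    <- arrhenius(p$rd25, 46390, t_leaf)
  kc    <- arrhenius(404.9, 79430, t_leaf)       # umol mol^-1
  ko    <- arrhenius(278.4, 36380, t_leaf)       # mmol mol^-1
  gstar <- arrhenius(42.75, 37830, t_leaf)       # umol mol^-1
  km    <- kc * (1 + p$o2 / ko)

  aq <- p$quantum_yield * par_leaf
  disc <- (aq + jmax)^2 - 4 * p$theta * aq * jmax
  j <- (aq + jmax - sqrt(pmax(disc, 0))) / (2 * p$theta)

  hs <- pmin(pmax(rh / 100, 0.1), 1)
  ci <- 0.7 * co2
  iters <- 0L
  a_net <- numeric(n); gs <- rep(p$g0, n)
  repeat {
    iters <- iters + 1L
    ac <- vcmax * (ci - gstar) / (ci + km)
    aj <- j * (ci - gstar) / (4 * ci + 8 * gstar)
    a_net <- pmin(ac, aj) - rd
    cs <- pmax(co2 - 1.37 * a_net / gb, 50)
    gs <- p$g0 + p$g1 * pmax(a_net, 0) * hs / cs
    ci_new <- co2 - a_net * (1.37 / gb + 1.6 / gs)
    ci_new <- pmin(pmax(ci_new, 1), 2 * co2 + 200)
    ci_next <- (ci + ci_new) / 2
    if (max(abs(ci_next - ci)) < p$ci_tol || iters >= p$ci_max_iter) {
      ci <- ci_next
      break
    }
    ci <- ci_next
  }
  list(a_net = a_net, gs = gs, ci = ci, iters = iters)
}

#' Linearized leaf energy balance
#'
#' Leaf-to-air temperature difference from absorbed shortwave with a
#' fixed evaporative fraction, sensible-heat and radiative
#' conductances; the offset is clamped to +/- 10 degC.
#'
#' @param sw_abs absorbed shortwave per leaf area (W m^-2).
#' @param t_air air temperature (degC).
#' @param gb boundary-layer conductance (mol m^-2 s^-1).
#' @param p gas_exchange config section (`evaporative_fraction`).
#' @return leaf temperature (degC).
#' @export
leaf_temperature <- function(sw_abs, t_air, gb, p) {
  tk <- t_air + 273.15
  gr <- 4 * 0.97 * 5.67e-8 * tk^3 / 29.3        # radiative conductance, mol m^-2 s^-1
  dt <- sw_abs * (1 - p$evaporative_fraction) / (29.3 * (gb + gr))
  t_air + pmin(pmax(dt, -10), 10)
}

#' Canopy environment constructor
#'
#' @param solar incident shortwave (W m^-2); vector over timesteps.
#' @param t_air air temperature (degC).
#' @param rh relative humidity (%).
#' @param wind wind speed (m s^-1).
#' @param co2 ambient CO2 (umol mol^-1).
#' @param lai green leaf area index (m^2 m^-2), scalar.
#' @param pd plant density (plants m^-2), scalar.
#' @return list of class `canopy_env`.
#' @export
canopy_env <- function(solar, t_air, rh, wind, co2, lai, pd) {
  stopifnot(all(solar >= 0), lai >= 0, pd >= 0)
  structure(list(solar = solar, t_air = t_air, rh = rh, wind = wind,
                 co2 = co2, lai = lai, pd = pd), class = "canopy_env")
}

#' Canopy assimilation via coupled gas exchange
#'
#' Partitions the canopy into sunlit and shaded big leaves by the
#' extinction coefficient `k` (sunlit leaf area
#' \eqn{(1 - e^{-k\,LAI})/k}), runs [leaf_gas_exchange()] per layer at
#' its absorbed PAR and energy-balance leaf temperature, sums net
#' assimilation over ground area, and converts mol CO2 to g CH2O
#' (x 30 g mol^-1) per plant. Night steps return the (negative) dark
#' respiration of the canopy; the carbon pool downstream is floored at
#' zero.
#'
#' @param env a [canopy_env()]; `solar`, `t_air`, `rh`, `wind`, `co2`
#'   may be vectors over timesteps.
#' @param p gas_exchange config section.
#' @param dt timestep (hours).
#' @return net assimilation per timestep, g CH2O plant^-1 (vector).
#' @export
canopy_assimilation <- function(env, p, dt = 1) {
  stopifnot(dt > 0)
  n <- length(env$solar)
  if (env$lai <= 0 || env$pd <= 0) return(rep(0, n))
  par0 <- p$par_per_sw * env$solar               # umol m^-2 ground s^-1
  k <- p$k; lai <- env$lai
  fint <- 1 - exp(-k * lai)
  l_sun <- fint / k
  l_sh <- max(lai - l_sun, 0)
  fd <- p$diffuse_fraction
  q_diffuse <- fd * par0 * fint / lai            # per-leaf diffuse component
  q_sun <- k * (1 - fd) * par0 + q_diffuse
  q_sh <- q_diffuse

  gb <- p$gb_ref * sqrt(pmax(env$wind, 0.5))
  sw_sun <- q_sun / p$par_per_sw * 0.8           # absorbed SW proxy, W m^-2
  sw_sh <- q_sh / p$par_per_sw * 0.8
  t_sun <- leaf_temperature(sw_sun, env$t_air, gb, p)
  t_sh <- leaf_temperature(sw_sh, env$t_air, gb, p)

  a_sun <- leaf_gas_exchange(q_sun, t_sun, env$rh, env$co2, gb, p)$a_net
  a_sh <- if (l_sh > 1e-9)
    leaf_gas_exchange(q_sh, t_sh, env$rh, env$co2, gb, p)$a_net
  else rep(0, n)

  a_canopy <- a_sun * l_sun + a_sh * l_sh        # umol CO2 m^-2 ground s^-1
  a_canopy * 3600 * dt * 1e-6 * 30 / env$pd      # g CH2O plant^-1
}

#' Canopy assimilation via radiation-use efficiency
#'
#' Beer-law light interception times a fixed radiation-use efficiency:
#' \eqn{A = RUE \cdot S (1 - e^{-k\,LAI})}, converted to per-plant.
#'
#' @param env a [canopy_env()].
#' @param rue radiation-use efficiency (g CH2O MJ^-1 intercepted), > 0.
#' @param k canopy extinction coefficient.
#' @param dt timestep (hours).
#' @return assimilation per timestep, g CH2O plant^-1 (vector).
#' @export
rue_assimilation <- function(env, rue, k = 0.6, dt = 1) {
  stopifnot(rue > 0, dt > 0)
  if (env$lai <= 0 || env$pd <= 0) return(rep(0, length(env$solar)))
  s_mj <- env$solar * 3600 * dt * 1e-6           # MJ m^-2 per step
  rue * s_mj * (1 - exp(-k * env$lai)) / env$pd
}
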