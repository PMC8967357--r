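#' @title Leaf morphology: elongation, area, senescence
#' @name morphology
#' @description Each appeared leaf elongates at a temperature-driven
#'   (and cold-injury-scaled) rate toward a rank-dependent potential
#'   final length, is translated to blade area by a width allometry,
#'   stays green for a stay-green-scaled physiological lifespan, then
#'   senesces. Green areas aggregate to per-plant green leaf area and,
#'   with plant density, to canopy LAI.
NULL

#' Rank-dependent potential final leaf length
#'
#' Gaussian-bell profile over leaf rank peaking at `lm_min` (the
#' minimum length of the longest leaf, 100 cm for the ND cultivar) at
#' rank `round(peak_rank_fraction * max_leaves)`, with a configurable
#' floor for the earliest/last ranks.
#'
#' @param rank leaf rank (1-based count); vectorized.
#' @param m morphology config section.
#' @param max_leaves total initiable leaves (from the phenology config).
#' @return potential final length (cm).
#' @export
leaf_potential_length <- function(rank, m, max_leaves = 16) {
  peak <- round(m$peak_rank_fraction * max_leaves)
  m$lm_min * (m$profile_floor + (1 - m$profile_floor) *
                exp(-((rank - peak)^2) / (2 * m$profile_sigma^2)))
}

#' Potential leaf elongation rate
#'
#' `LER_p = LER_max x f(T)` with the morphology module's beta thermal
#' response; cold injury later scales this potential to the actual rate
#' via [apply_injury()].
#'
#' @param t_air air temperature (degC); vectorized.
#' @param m morphology config section (`ler_max`, cardinal
#'   temperatures).
#' @return LER_p (cm d^-1) in \[0, `ler_max`\].
#' @export
potential_ler <- function(t_air, m) {
  m$ler_max * thermal_response(t_air, m$t_base, m$t_opt, m$t_ceil)
}

#' Grow a leaf by one step
#'
#' Length increments by `ler * dt`, truncated exactly at the potential
#' final length.
#'
#' @param length current blade length (cm); vectorized.
#' @param potential potential final length (cm).
#' @param ler actual elongation rate (cm d^-1, >= 0, already
#'   injury-scaled).
#' @param dt step (days).
#' @return new length (cm), `<= potential`.
#' @export
grow_leaf <- function(length, potential, ler, dt = 1) {
  stopifnot(all(ler >= 0), dt > 0)
  pmin(length + ler * dt, potential)
}

#' Blade area from length
#'
#' Allometry `area = length x width x form_factor` with width
#' proportional to the leaf's potential final length
#' (`width_factor * potential`), so longer-ranked leaves are also
#' wider.
#'
#' @param length blade length (cm).
#' @param potential potential final length (cm).
#' @param m morphology config section (`width_factor`, `form_factor`).
#' @return one-sided blade area (cm^2).
#' @export
leaf_area <- function(length, potential, m) {
  length * (m$width_factor * potential) * m$form_factor
}

#' Green fraction of a leaf at a physiological age
#'
#' A leaf is fully green until `green_plateau_fraction` of its lifespan
#' `sg * green_span` (physiological days, i.e. days weighted by the
#' thermal response), then declines linearly to zero. The stay-green
#' multiplier `sg` scales the whole green duration proportionally.
#'
#' @param p_age physiological age since appearance (thermal-weighted
#'   days); vectorized.
#' @param m morphology config section (`sg`, `green_span`,
#'   `green_plateau_fraction`).
#' @return green fraction in \[0,1\], non-increasing in age.
#' @export
green_fraction <- function(p_age, m) {
  span <- m$sg * m$green_span
  plateau <- m$green_plateau_fraction * span
  ifelse(p_age <= plateau, 1,
         pmax((span - p_age) / (span - plateau), 0))
}

#' Age and senesce a set of leaves
#'
#' Advances physiological age by `d_age` for all appeared leaves,
#' recomputes areas and green fractions, and reports total green area.
#'
#' @param leaves data.frame with columns `rank`, `length`, `potential`,
#'   `p_age` (see [run_season()] internals); one row per appeared leaf.
#' @param d_age physiological-age increment this step (thermal-weighted
#'   days, >= 0).
#' @param m morphology config section.
#' @return the updated data.frame with `area`, `green_frac` and an
#'   attribute `green_area` (cm^2 plant^-1, sum of `area *
#'   green_frac`).
#' @export
senesce <- function(leaves, d_age, m) {
  stopifnot(d_age >= 0)
  if (nrow(leaves)) {
    leaves$p_age <- leaves$p_age + d_age
    leaves$area <- leaf_area(leaves$length, leaves$potential, m)
    leaves$green_frac <- green_fraction(leaves$p_age, m)
  } else {
    leaves$area <- numeric(0); leaves$green_frac <- numeric(0)
  }
  attr(leaves, "green_area") <- sum(leaves$area * leaves$green_frac)
  leaves
}

#' Leaf area index from per-plant green area
#'
#' @param green_area green leaf area (cm^2 plant^-1, >= 0).
#' @param pd plant density (plants m^-2, >= 0).
#' @return LAI (m^2 m^-2) = `green_area * 1e-4 * pd`.
#' @export
lai <- function(green_area, pd) {
  stopifnot(all(green_area >= 0), all(pd >= 0))
  green_area * 1e-4 * pd
}
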