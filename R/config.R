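#' Default simulation configuration
#'
#' Builds the full nested configuration used by [run_season()] and the
#' experiment harness. Defaults describe the southern-type Namdo (ND)
#' cultivar: phyllochron and storage parameters, cold stress thresholds,
#' leaf development constants, gas-exchange constants, and the
#' stage-by-organ partitioning table.
#'
#' Sections:
#' \describe{
#'   \item{phenology}{`ltar_max_a` (d^-1), `sd_m` (d), `alpha` (d^-1),
#'     `n_g`, `iln`, storage temperature `st` (degC, retained but inert:
#'     only storage duration enters the sigmoid), `seed_harvest_date`
#'     (MM-DD), reproductive onset thermal time `repro_onset_gdd`
#'     (degC d above `gdd_base` after emergence), `scape_phyllochrons`,
#'     `max_leaves`, and the beta thermal response (`t_base`, `t_opt`,
#'     `t_ceil`, degC) applied to the leaf tip appearance rate.}
#'   \item{coldstress}{`t_c_i`, `cold_a`, `cold_b`, `t_c_d`, `cold_s`,
#'     `pd_0` (plants m^-2).}
#'   \item{morphology}{`ler_max` (cm d^-1), `lm_min` (cm), `sg`,
#'     `expansion_days`, leaf length profile shape, width/form factors
#'     for the length-to-area allometry, senescence spans (physiological
#'     days), and the elongation thermal response.}
#'   \item{gas_exchange}{Farquhar/Ball-Berry constants (flagged
#'     estimates for garlic), canopy extinction coefficient `k`, PAR
#'     conversion, diffuse fraction, boundary-layer settings.}
#'   \item{allocation}{`y_g`, per-organ maintenance coefficients
#'     (g g^-1 d^-1 at 25 degC), `q10`, `initial_pool` (g),
#'     `scape_visible_fraction`, `partition_table` (6 stages x 5 organs).}
#'   \item{simulation}{`carbon_source` ("coupled" or "rue"), `rue`
#'     (g MJ^-1), planting/harvest dates, bulb moisture fraction,
#'     `scape_removal` ("none", "immediate", or "date:<MM-DD>").}
#' }
#'
#' @param ... named overrides merged recursively onto the defaults, e.g.
#'   `garlic_config(coldstress = list(pd_0 = 60))`.
#' @return A nested list of class `garlic_config`.
#' @examples
#' cfg <- garlic_config()
#' cfg$phenology$ltar_max_a
#' cfg <- garlic_config(simulation = list(carbon_source = "rue"))
#' @export
garlic_config <- function(...) {
  cfg <- list(
    phenology = list(
      ltar_max_a = 0.4421,
      sd_m       = 117.7523,
      alpha      = 0.0256,
      n_g        = 10,
      iln        = 6,
      st         = 8,
      seed_harvest_date = "06-30",
      repro_onset_gdd   = 1000,
      gdd_base          = 4,
      scape_phyllochrons = 3,
      max_leaves = 16,
      t_base = 0, t_opt = 22, t_ceil = 34
    ),
    coldstress = list(
      t_c_i  = 0,
      cold_a = -0.1,
      cold_b = 1.6,
      t_c_d  = -15,
      cold_s = 0.9,
      pd_0   = 50
    ),
    morphology = list(
      ler_max = 5.56,
      lm_min  = 100,
      sg      = 1.5,
      expansion_days = 18,
      peak_rank_fraction = 0.75,
      profile_sigma      = 4,
      profile_floor      = 0.25,
      width_factor = 0.03,
      form_factor  = 0.75,
      green_span   = 50,
      green_plateau_fraction = 0.7,
      t_base = 0, t_opt = 20, t_ceil = 35
    ),
    gas_exchange = list(
      vcmax25 = 90,  jmax25 = 160, rd25 = 1.2,
      theta = 0.7, quantum_yield = 0.24,
      g0 = 0.02, g1 = 9,
      gb_ref = 1.2,
      k = 0.6,
      par_per_sw = 2.3, par_fraction = 0.5,
      diffuse_fraction = 0.2,
      evaporative_fraction = 0.5,
      o2 = 210,
      ci_tol = 1e-3, ci_max_iter = 100
    ),
    allocation = list(
      y_g = 0.75,
      maintenance = c(root = 0.010, leaf = 0.015, sheath = 0.008,
                      scape = 0.008, bulb = 0.002),
      q10 = 2,
      initial_pool = 2,
      scape_visible_fraction = 1.0,
      partition_table = default_partition_table()
    ),
    simulation = list(
      carbon_source = "coupled",
      rue = 2.0,
      planting_date = NULL,
      harvest_date  = "05-15",
      bulb_moisture = 0.85,
      scape_removal = "immediate",
      co2 = NULL
    )
  )
  dots <- list(...)
  if (length(dots)) {
    stopifnot(!is.null(names(dots)), all(nzchar(names(dots))))
    cfg <- modify_list_deep(cfg, dots)
  }
  class(cfg) <- "garlic_config"
  cfg
}

#' Read a configuration file
#'
#' Reads a YAML key-value document and merges it onto [garlic_config()]
#' defaults, so a file needs to state only the values it changes.
#'
#' @param path path to a YAML file whose top-level keys are config
#'   sections (`phenology`, `coldstress`, ...).
#' @return A `garlic_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ov <- yaml::read_yaml(path)
  if (is.null(ov)) return(garlic_config())
  if (!is.null(ov$allocation$partition_table)) {
    pt <- ov$allocation$partition_table
    if (!is.matrix(pt)) {
      pt <- do.call(rbind, lapply(pt, unlist))
      colnames(pt) <- organ_names()
      pt <- pt[stage_names(), , drop = FALSE]
    }
    ov$allocation$partition_table <- pt
  }
  do.call(garlic_config, ov)
}

# recursive modifyList that descends into plain named lists only
modify_list_deep <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- modify_list_deep(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' @export
print.garlic_config <- function(x, ...) {
  cat("<garlic_config>\n")
  for (sec in names(x)) {
    keys <- names(x[[sec]])
    cat(sprintf("  %-16s %s\n", sec, paste(keys, collapse = ", ")))
  }
  invisible(x)
}

stage_names <- function() c("seed", "vegetative", "R1", "R2", "R3", "death")
organ_names <- function() c("root", "leaf", "sheath", "scape", "bulb")
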