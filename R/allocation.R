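#' @title Carbon pool and stage-dependent partitioning
#' @name allocation
#' @description Assimilated carbon accumulates in a pool (g CH2O
#'   plant^-1). Each day the supply from the pool, less maintenance
#'   respiration, is converted to structural growth at the carbohydrate
#'   synthesis efficiency Y_g and split among root, leaf, sheath, scape
#'   and bulb by a stage-by-organ partitioning table.
NULL

#' Default partitioning table
#'
#' Rows are developmental stages (`seed`, `vegetative`, `R1`, `R2`,
#' `R3`, `death`), columns destination organs (`root`, `leaf`,
#' `sheath`, `scape`, `bulb`). Living-stage rows sum to 1, the death
#' row is all zeros, and the scape column is zero in the vegetative
#' stage (no scape yet) and in R3 (organ removed). The numeric
#' coefficients are teleonomic estimates — root/leaf/sheath-heavy
#' early, progressively bulb-dominant through the reproductive stages —
#' after scape removal the mature sheath stops growing (R3 sheath
#' coefficient 0), so stalk biomass peaks and then falls — and are
#' fully configurable; every conservation property holds for any valid
#' table.
#'
#' @return 6 x 5 numeric matrix with stage rownames and organ colnames.
#' @export
default_partition_table <- function() {
  m <- rbind(
    seed       = c(0.45, 0.35, 0.20, 0.00, 0.00),
    vegetative = c(0.15, 0.45, 0.30, 0.00, 0.10),
    R1         = c(0.05, 0.15, 0.15, 0.15, 0.50),
    R2         = c(0.02, 0.05, 0.08, 0.25, 0.60),
    R3         = c(0.02, 0.03, 0.00, 0.00, 0.95),
    death      = c(0.00, 0.00, 0.00, 0.00, 0.00)
  )
  colnames(m) <- organ_names()
  m
}

#' Validate a partitioning table
#'
#' Checks the structural invariants: entries in \[0,1\], living-stage
#' rows summing to 1, all-zero death row, and zero scape coefficient in
#' the vegetative and R3 stages.
#'
#' @param table 6 x 5 matrix as in [default_partition_table()].
#' @return the table, invisibly; errors describe the first violation.
#' @export
validate_partition_table <- function(table) {
  if (!all(stage_names() %in% rownames(table)))
    stop("partition table must have rows ", paste(stage_names(), collapse = ", "))
  if (!all(organ_names() %in% colnames(table)))
    stop("partition table must have columns ", paste(organ_names(), collapse = ", "))
  if (any(table < 0 | table > 1)) stop("partition coefficients must lie in [0,1]")
  living <- setdiff(stage_names(), "death")
  rs <- rowSums(table[living, , drop = FALSE])
  if (any(abs(rs - 1) > 1e-8))
    stop("living-stage rows must sum to 1; offending stage: ",
         living[which(abs(rs - 1) > 1e-8)[1]])
  if (any(table["death", ] != 0)) stop("death row must be all zeros")
  if (table["vegetative", "scape"] != 0)
    stop("scape coefficient must be 0 in the vegetative stage")
  if (table["R3", "scape"] != 0)
    stop("scape coefficient must be 0 in R3 (organ removed)")
  invisible(table)
}

#' Maintenance respiration demand
#'
#' Q10 formulation: per-organ coefficient (g g^-1 d^-1 at 25 degC)
#' times biomass, scaled by `q10^((T - 25)/10)`.
#'
#' @param biomass named numeric vector of organ dry masses (g).
#' @param t_air air temperature (degC).
#' @param p allocation config section (`maintenance`, `q10`).
#' @return maintenance demand (g CH2O d^-1).
#' @export
maintenance_respiration <- function(biomass, t_air, p) {
  coef <- p$maintenance[names(biomass)]
  sum(coef * biomass) * p$q10^((t_air - 25) / 10)
}

#' Step the carbon pool and compute the actual allocation rate
#'
#' Incoming assimilate (possibly negative at night) joins the pool,
#' which is floored at zero. The supply rate drains the whole pool over
#' the step; maintenance respiration is paid first (capped by what the
#' pool holds), and the remainder is converted to growth at efficiency
#' Y_g: `allocation = max(supply - maintenance, 0) * y_g`. The carbon
#' drawn for growth is `allocation / y_g`; the (1 - Y_g) share is
#' growth respiration.
#'
#' @param pool current pool mass (g CH2O plant^-1, >= 0).
#' @param assimilate net assimilate this step (g CH2O plant^-1).
#' @param biomass named organ dry-mass vector (g).
#' @param t_air daily mean air temperature (degC).
#' @param p allocation config section.
#' @param dt step length (days).
#' @return list: `pool` (updated, >= 0), `allocation` (g d^-1),
#'   `maintenance_paid` (g), `growth_c` (g drawn for growth, =
#'   allocation*dt/y_g), and `unmet_respiration` (g of night
#'   respiration the empty pool could not cover; keeps the season
#'   carbon balance exact).
#' @export
step_pool <- function(pool, assimilate, biomass, t_air, p, dt = 1) {
  stopifnot(pool >= 0, dt > 0)
  unmet <- max(-(pool + assimilate), 0)
  avail <- pool + assimilate + unmet             # pool floored at zero
  maint_demand <- maintenance_respiration(biomass, t_air, p) * dt
  maint_paid <- min(maint_demand, avail)
  remainder <- avail - maint_paid
  allocation <- remainder / dt * p$y_g           # g d^-1
  growth_c <- remainder                          # allocation*dt / y_g
  list(pool = 0, allocation = allocation,
       maintenance_paid = maint_paid, growth_c = growth_c,
       unmet_respiration = unmet)
}

#' Partition an allocation rate among organs
#'
#' Splits `allocation * dt` by the partitioning-table row for the
#' current stage. Conservation is exact: organ increments sum to the
#' allocated mass.
#'
#' @param allocation actual allocation rate (g d^-1, >= 0).
#' @param stage stage name (a row of the table).
#' @param table partitioning table.
#' @param dt step length (days).
#' @return named numeric vector of per-organ increments (g, >= 0).
#' @export
partition <- function(allocation, stage, table, dt = 1) {
  if (!stage %in% rownames(table))
    stop("no partitioning row for stage '", stage, "'")
  stopifnot(allocation >= 0, dt > 0)
  row <- table[stage, organ_names()]
  total <- allocation * dt
  inc <- row * total
  # pin the largest coefficient so the increments sum exactly
  s <- sum(row)
  if (s > 0) {
    i <- which.max(row)
    inc[i] <- total * s - sum(inc[-i])
  }
  inc
}

#' Remove the scape
#'
#' Zeroes the visible fraction of the scape organ (default all of it)
#' and reports the removed mass as harvested scape yield; the plant
#' advances from R2 to R3. Calling outside R2 is a state error.
#'
#' @param biomass named organ dry-mass vector (g).
#' @param stage current stage (must be `"R2"`).
#' @param visible_fraction fraction of scape mass cut (default 1).
#' @return list: `biomass` (scape reduced), `removed` (g), `stage`
#'   (`"R3"`).
#' @export
remove_scape <- function(biomass, stage, visible_fraction = 1) {
  if (!identical(stage, "R2"))
    stop("scape removal is only valid in stage R2 (current: ", stage, ")")
  stopifnot(visible_fraction >= 0, visible_fraction <= 1)
  removed <- biomass[["scape"]] * visible_fraction
  biomass[["scape"]] <- biomass[["scape"]] - removed
  list(biomass = biomass, removed = removed,
       stage = advance_stage(stage, "R3"))
}
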