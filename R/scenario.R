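# Scenario drivers: graphite-addition sweeps, temperature sweeps, H/C/N/O
# sensitivity grids, the QFM oxygen-fugacity diagnostic, and the methyl
# isocyanide estimator.

#' Scenario configuration
#'
#' @param T_celsius magma temperature in degrees Celsius
#' @param P total pressure in bar
#' @param base_composition a [gas_state()] or [element_budget()]; default the
#'   printed fiducial gas ([table1_gas()])
#' @param nitrogen_fraction N2 mixing-ratio share of the base gas (default
#'   0.057); when it differs from the base gas's N2 share, the N2 ratio is
#'   rescaled and the other species renormalized proportionally
#' @param graphite_grid added-carbon atom fractions (of total atoms) to sweep
#' @param model which branch(es) to run: the equilibrium branch uses the
#'   equilibrium-variant graphite vapor pressure, the kinetics branch the
#'   kinetics variant (their endpoints differ only through that choice; see
#'   the package vignette)
#' @param hc3n HC3N thermochemistry source (see [solve_gas_equilibrium()])
#' @return object of class `scenario_config`
#' @export
scenario_config <- function(T_celsius = 1700, P = 100,
                            base_composition = table1_gas(),
                            nitrogen_fraction = 0.057,
                            graphite_grid = seq(0, 0.3, by = 0.02),
                            model = c("both", "equilibrium", "kinetics"),
                            hc3n = c("eq6", "table")) {
  model <- match.arg(model)
  hc3n <- match.arg(hc3n)
  if (nitrogen_fraction < 0 || nitrogen_fraction >= 1)
    stop("nitrogen_fraction must be in [0, 1)")
  if (length(graphite_grid) == 0L || is.unsorted(graphite_grid))
    stop("graphite_grid must be non-empty and sorted")
  structure(list(T_celsius = T_celsius, P = P,
                 base_composition = base_composition,
                 nitrogen_fraction = nitrogen_fraction,
                 graphite_grid = graphite_grid, model = model, hc3n = hc3n),
            class = "scenario_config")
}

# element budget of a config, with the nitrogen share applied
.config_budget <- function(cfg, table = thermo_table()) {
  base <- cfg$base_composition
  if (inherits(base, "element_budget")) return(base)
  x <- base$mixing_ratios
  n2 <- if ("N2" %in% names(x)) x[["N2"]] else 0
  # the printed fiducial gas normalizes its 5.7% N2 to 5.717%; treat
  # sub-0.1%-point differences as "unchanged"
  if (abs(n2 - cfg$nitrogen_fraction) > 1e-3) {
    others <- setdiff(names(x), "N2")
    x[others] <- x[others] * (1 - cfg$nitrogen_fraction) / sum(x[others])
    x["N2"] <- cfg$nitrogen_fraction
    base <- gas_state(x / sum(x), base$T, base$P)
  }
  mixing_ratios_to_elements(base, table)
}

.budget_with_added_carbon <- function(budget, f) {
  ab <- budget$abundances / sum(budget$abundances)
  A <- f / (1 - f)
  ab[["C"]] <- (if ("C" %in% names(ab)) ab[["C"]] else 0) + A
  element_budget(ab)
}

.branch_variants <- function(model) {
  switch(model,
         both = c(equilibrium = "equilibrium", kinetics = "kinetics"),
         equilibrium = c(equilibrium = "equilibrium"),
         kinetics = c(kinetics = "kinetics"))
}

# one sweep row: model label + equilibrate_with_graphite result -> named list
.sweep_row <- function(res, cfg) {
  qfm <- tryCatch(qfm_deviation(res$gas)$deviation, error = function(e) NA_real_)
  c(list(saturated = res$saturated, graphite_fraction = res$graphite_fraction,
         qfm_deviation = qfm), as.list(res$gas$mixing_ratios))
}

.rows_to_df <- function(rows) {
  species <- unique(unlist(lapply(rows, names)))
  df <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(species, names(r))] <- NA
    as.data.frame(r[species], check.names = FALSE)
  }))
  rownames(df) <- NULL
  df
}

#' Graphite-addition sweep
#'
#' Runs the selected model branch(es) over the configured grid of added
#' graphite (carbon atom fraction of total atoms), recording every species'
#' mixing ratio, the QFM deviation, the saturation flag and the condensed
#' carbon fraction at each grid point.  Solver errors at a grid point are
#' annotated with the point and re-raised.
#'
#' @param cfg a [scenario_config()]
#' @param table thermo table
#' @return a data frame of class `sweep_result` with one row per (grid
#'   point, model branch)
#' @export
graphite_sweep <- function(cfg = scenario_config(), table = thermo_table()) {
  T <- celsius_to_kelvin(cfg$T_celsius)
  budget0 <- .config_budget(cfg, table)
  variants <- .branch_variants(cfg$model)
  rows <- list()
  for (f in cfg$graphite_grid) {
    budget <- .budget_with_added_carbon(budget0, f)
    for (mdl in names(variants)) {
      res <- tryCatch(
        equilibrate_with_graphite(budget, T, cfg$P, variant = variants[[mdl]],
                                  table = table, hc3n = cfg$hc3n),
        error = function(e) stop("graphite_sweep failed at added fraction ",
                                 f, " (", mdl, " branch): ",
                                 conditionMessage(e), call. = FALSE))
      rows <- c(rows, list(c(list(added_fraction = f, model = mdl),
                             .sweep_row(res, cfg))))
    }
  }
  out <- .rows_to_df(rows)
  class(out) <- c("sweep_result", class(out))
  attr(out, "axis") <- "added_fraction"
  out
}

#' Temperature sweep at graphite saturation
#'
#' Solves the graphite-saturated equilibrium of the configured composition
#' at each temperature (carbon is added well beyond the saturation
#' threshold; the saturated gas composition is independent of the excess).
#'
#' @param cfg a [scenario_config()]
#' @param T_grid_celsius temperatures in degrees Celsius
#' @param table thermo table
#' @return a `sweep_result` data frame, one row per (temperature, branch)
#' @export
temperature_sweep <- function(cfg = scenario_config(),
                              T_grid_celsius = seq(1300, 1800, by = 100),
                              table = thermo_table()) {
  budget0 <- .config_budget(cfg, table)
  variants <- .branch_variants(cfg$model)
  rows <- list()
  for (Tc in T_grid_celsius) {
    T <- celsius_to_kelvin(Tc)
    budget <- .budget_with_added_carbon(budget0, 0.5)
    for (mdl in names(variants)) {
      res <- tryCatch(
        equilibrate_with_graphite(budget, T, cfg$P, variant = variants[[mdl]],
                                  table = table, hc3n = cfg$hc3n),
        error = function(e) stop("temperature_sweep failed at ", Tc,
                                 " degC (", mdl, " branch): ",
                                 conditionMessage(e), call. = FALSE))
      rows <- c(rows, list(c(list(T_celsius = Tc, model = mdl),
                             .sweep_row(res, cfg))))
    }
  }
  out <- .rows_to_df(rows)
  class(out) <- c("sweep_result", class(out))
  attr(out, "axis") <- "T_celsius"
  out
}

#' H/C/N/O sensitivity grid
#'
#' Cross product of element budgets, temperatures and pressures, each solved
#' with graphite equilibration; returns a tidy long-format table.  Grids
#' default to coarse (desk-scale) resolution; failed points are retained
#' with `NA` mixing ratios and the error message.
#'
#' @param element_grids named list of abundance vectors to cross (e.g.
#'   `list(H = c(0.5, 1), C = c(0.3, 0.6), N = 0.114, O = 1.07)`)
#' @param T_grid_celsius temperatures (degC)
#' @param P_grid pressures (bar)
#' @param variant vapor-pressure variant
#' @param species species whose mixing ratios are reported (default: the
#'   nitrile/isonitrile set plus major species)
#' @param hc3n HC3N thermochemistry source
#' @param table thermo table
#' @return long data frame: element abundances, `T_celsius`, `P`,
#'   `saturated`, `species`, `mixing_ratio`, `error`
#' @export
sensitivity_grid <- function(element_grids,
                             T_grid_celsius = c(1300, 1500, 1700),
                             P_grid = c(1, 100),
                             variant = c("equilibrium", "kinetics"),
                             species = c("HCN", "HNC", "HC3N", "C4H2", "CO",
                                         "CO2", "H2", "H2O", "N2", "CH4"),
                             hc3n = c("eq6", "table"),
                             table = thermo_table()) {
  variant <- match.arg(variant)
  hc3n <- match.arg(hc3n)
  stopifnot(all(lengths(element_grids) >= 1))
  combos <- expand.grid(c(element_grids,
                          list(T_celsius = T_grid_celsius, P = P_grid)),
                        KEEP.OUT.ATTRS = FALSE)
  out <- list()
  for (i in seq_len(nrow(combos))) {
    row <- combos[i, , drop = FALSE]
    ab <- unlist(row[names(element_grids)])
    names(ab) <- names(element_grids)
    res <- tryCatch(
      equilibrate_with_graphite(element_budget(ab),
                                celsius_to_kelvin(row$T_celsius), row$P,
                                variant = variant, table = table,
                                hc3n = hc3n),
      error = function(e) e)
    if (inherits(res, "error")) {
      out[[i]] <- data.frame(row, saturated = NA, species = species,
                             mixing_ratio = NA_real_,
                             error = conditionMessage(res),
                             check.names = FALSE, row.names = NULL)
    } else {
      x <- res$gas$mixing_ratios
      out[[i]] <- data.frame(row, saturated = res$saturated,
                             species = species,
                             mixing_ratio = unname(x[species]),
                             error = NA_character_,
                             check.names = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Oxygen-fugacity deviation from the QFM buffer
#'
#' log10 fO2 from the O2 partial pressure of a gas state, referenced to a
#' standard quartz-fayalite-magnetite parameterization
#' (`log10 fO2(QFM) = A/T + B + C (P-1)/T`, Frost 1991 coefficients by
#' default) at the same temperature and pressure.  Only relative deviations
#' are meaningful at magmatic temperatures well above fayalite stability.
#'
#' @param gas a [gas_state()] containing an `O2` mixing ratio (solve for
#'   equilibrium first if O2 is absent or zero)
#' @param coef QFM parameterization coefficients `c(A, B, C)`
#' @param parameterization label recorded in the output
#' @return list with `log_fO2`, `qfm_reference`, `deviation` (log10 units),
#'   `parameterization`
#' @export
qfm_deviation <- function(gas, coef = c(A = -25096.3, B = 8.735, C = 0.110),
                          parameterization = "Frost1991") {
  xO2 <- gas$mixing_ratios["O2"]
  if (is.na(xO2) || xO2 <= 0)
    stop("gas state has no O2; run an equilibrium solve first")
  log_fO2 <- log10(xO2 * gas$P)
  ref <- coef[["A"]] / gas$T + coef[["B"]] + coef[["C"]] * (gas$P - 1) / gas$T
  list(log_fO2 = unname(log_fO2), qfm_reference = ref,
       deviation = unname(log_fO2 - ref), parameterization = parameterization)
}

#' Methyl isocyanide concentration estimate
#'
#' Estimates the CH3NC mixing ratio from the mass action of
#' HCN + CH4 -> CH3NC + H2:
#' `[CH3NC] = exp(-dGr/RT) [HCN][CH4]/[H2]`.  CH3NC is estimator-only and is
#' never inserted into the reaction network or the equilibrium species set.
#'
#' @param T temperature (K)
#' @param hcn,ch4,h2 mixing ratios (fractions in `[0,1]`; `h2 > 0`)
#' @param delta_g reaction Gibbs energy in kJ/mol; defaults to
#'   [reaction_delta_g()] of the reaction above at `T` from the packaged
#'   table
#' @param table thermo table
#' @return estimated CH3NC mixing ratio
#' @export
ch3nc_estimate <- function(T, hcn, ch4, h2, delta_g = NULL,
                           table = thermo_table()) {
  if (h2 <= 0) stop("H2 mixing ratio must be positive")
  vals <- c(hcn = hcn, ch4 = ch4, h2 = h2)
  if (any(vals < 0) || any(vals > 1))
    stop("mixing ratios must lie in [0, 1]")
  if (is.null(delta_g))
    delta_g <- reaction_delta_g(
      reaction_stoichiometry(c(HCN = 1, CH4 = 1), c(CH3NC = 1, H2 = 1)),
      table, T)
  exp(-delta_g * 1e3 / (.RGAS * T)) * hcn * ch4 / h2
}
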