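# Gas-phase chemical equilibrium by the element-potential method.
#
# Unknowns are the log partial pressures of the monatomic species (one
# element potential per element) plus a log atom-scale; every molecule's
# partial pressure follows from its formation mass-action constant,
#   ln p_s = ln K_s + sum_e nu_es * lambda_e        (pressures in bar).
# Element-ratio conservation and total pressure close the system, which is
# solved by a damped Newton iteration on logarithmic residuals with
# temperature continuation from 6000 K (where atoms dominate and any initial
# guess converges).

# formation-from-atoms ln K for each species at temperature T.
# hc3n = "eq6" drives HC3N with the five-term mass-action fit instead of the
# polynomial table.
.lnK_formation <- function(table, species, T, hc3n = "eq6") {
  g_atoms <- vapply(unique(unlist(lapply(species, function(s)
    names(.get_species(table, s)$composition)))), function(el)
      .species_g_rt(.get_species(table, el), T), numeric(1))
  out <- vapply(species, function(s) {
    if (identical(s, "HC3N") && identical(hc3n, "eq6"))
      return(hc3n_ln_mass_action(T))
    comp <- .get_species(table, s)$composition
    sum(g_atoms[names(comp)] * comp) - .species_g_rt(.get_species(table, s), T)
  }, numeric(1))
  names(out) <- species
  out
}

# default gas-phase species set: everything in the table compatible with the
# elements present
.species_for_elements <- function(table, elements) {
  gas <- Filter(function(s) s$phase == "gas", table$species)
  names(gas)[vapply(gas, function(s)
    all(names(s$composition) %in% elements), logical(1))]
}

.default_control <- function(control = list()) {
  utils::modifyList(list(tol = 1e-13, maxit = 200, restarts = 5,
                         continuation_steps = 8, step_cap = 10), control)
}

# One damped Newton solve at fixed T.  lambda: named log atom pressures;
# clamped elements are held fixed.  Returns list(lambda, ln_beta, ok, p).
.newton_solve <- function(nu, lnK, b, P, lambda, ln_beta, free, control) {
  resid <- function(lambda, ln_beta) {
    lnp <- pmin(lnK + drop(nu %*% lambda), 600)
    p <- exp(lnp)
    atoms <- drop(crossprod(nu, p))
    beta <- exp(ln_beta)
    Fv <- c(log(atoms[free] / (beta * b[free])), log(sum(p) / P))
    list(F = Fv, p = p, atoms = atoms)
  }
  r <- resid(lambda, ln_beta)
  for (it in seq_len(control$maxit)) {
    f0 <- max(abs(r$F))
    if (!is.finite(f0)) return(list(ok = FALSE, lambda = lambda,
                                    ln_beta = ln_beta, p = r$p))
    if (f0 < control$tol)
      return(list(ok = TRUE, lambda = lambda, ln_beta = ln_beta, p = r$p,
                  atoms = r$atoms))
    nf <- length(free)
    J <- matrix(0, nf + 1L, nf + 1L)
    for (i in seq_len(nf)) {
      k <- free[i]
      J[i, seq_len(nf)] <- vapply(free, function(l)
        sum(nu[, k] * nu[, l] * r$p), numeric(1)) / r$atoms[k]
      J[i, nf + 1L] <- -1
    }
    J[nf + 1L, seq_len(nf)] <- vapply(free, function(l)
      sum(nu[, l] * r$p), numeric(1)) / sum(r$p)
    dx <- tryCatch(solve(J, -r$F), error = function(e) NULL)
    if (is.null(dx)) return(list(ok = FALSE, lambda = lambda,
                                 ln_beta = ln_beta, p = r$p))
    mx <- max(abs(dx))
    if (mx > control$step_cap) dx <- dx * control$step_cap / mx
    step <- 1; improved <- FALSE
    for (ls in 1:50) {
      lam2 <- lambda; lam2[free] <- lambda[free] + step * dx[seq_along(free)]
      lb2 <- ln_beta + step * dx[length(dx)]
      r2 <- resid(lam2, lb2)
      if (all(is.finite(r2$F)) &&
          sum(r2$F^2) < sum(r$F^2) * (1 - 1e-4 * step)) {
        lambda <- lam2; ln_beta <- lb2; r <- r2; improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) return(list(ok = FALSE, lambda = lambda,
                               ln_beta = ln_beta, p = r$p, atoms = r$atoms))
  }
  list(ok = FALSE, lambda = lambda, ln_beta = ln_beta, p = r$p,
       atoms = r$atoms)
}

# Full solve with temperature continuation and perturbed restarts.
# clamp: named vector of fixed log atom pressures (e.g. c(C = log(pvap))).
.solve_core <- function(budget, T, P, species, table, clamp = NULL,
                        hc3n = "eq6", control = list()) {
  control <- .default_control(control)
  ab <- budget$abundances
  elements <- names(ab)[ab > 0]
  if (!is.null(clamp)) elements <- union(elements, names(clamp))
  if (is.null(species)) species <- .species_for_elements(table, elements)
  species <- species[vapply(species, function(s)
    all(names(.get_species(table, s)$composition) %in% elements), logical(1))]
  if (length(species) == 0L) stop("no species available for elements ",
                                  paste(elements, collapse = ","))
  nu <- do.call(rbind, lapply(species, function(s) {
    comp <- .get_species(table, s)$composition
    out <- setNames(numeric(length(elements)), elements)
    out[names(comp)] <- comp
    out
  }))
  dimnames(nu) <- list(species, elements)
  b <- setNames(numeric(length(elements)), elements)
  b[names(ab)] <- ab
  b <- b / sum(b)
  # Elements whose columns of the formula matrix are linearly dependent on
  # the others (e.g. C and N when carbon and nitrogen only ever appear
  # together as CN groups) leave the corresponding potential as a pure
  # gauge freedom; fix the redundant potentials at their initial value and
  # drop their (implied) conservation equations.
  qrnu <- qr(nu)
  independent <- elements[sort(qrnu$pivot[seq_len(qrnu$rank)])]
  free <- which(elements %in% independent &
                  !(elements %in% names(clamp)) & b > 0)
  if (length(free) == 0L)
    stop("equilibrium solve needs at least one unclamped element with ",
         "non-zero abundance")
  attempt <- function(lam0, lb0, steps) {
    Tpath <- exp(seq(log(6000), log(T), length.out = steps))
    lambda <- lam0; ln_beta <- lb0
    for (Tc in Tpath) {
      lnK <- .lnK_formation(table, species, Tc, hc3n)
      if (!is.null(clamp)) lambda[names(clamp)] <- clamp
      res <- .newton_solve(nu, lnK, b, P, lambda, ln_beta, free, control)
      lambda <- res$lambda; ln_beta <- res$ln_beta
    }
    if (!is.null(clamp)) lambda[names(clamp)] <- clamp
    lnK <- .lnK_formation(table, species, T, hc3n)
    .newton_solve(nu, lnK, b, P, lambda, ln_beta, free, control)
  }
  lam0 <- setNames(log(pmax(b, 1e-12) * P), elements)
  if (!is.null(clamp)) lam0[names(clamp)] <- clamp
  steps <- control$continuation_steps
  res <- attempt(lam0, log(P), steps)
  tries <- 0L
  while (!res$ok && tries < control$restarts) {
    tries <- tries + 1L
    # escalate the continuation resolution first, then perturb the start
    steps <- min(80L, steps * 2L)
    pert <- if (tries <= 2L) 0 else
      .with_seed(1000L + tries,  # deterministic, RNG state preserved
                 stats::rnorm(length(lam0), 0, 2))
    res <- attempt(lam0 + pert, log(P), steps)
  }
  if (!res$ok) {
    resid <- drop(crossprod(nu, res$p))[free] / (exp(res$ln_beta) * b[free]) - 1
    stop("equilibrium solver did not converge after ", control$restarts,
         " restarts; element residuals: ",
         paste(sprintf("%s=%.2e", elements[free], resid), collapse = " "),
         call. = FALSE)
  }
  atoms <- drop(crossprod(nu, res$p))
  beta <- exp(res$ln_beta)
  residuals <- setNames(rep(NA_real_, length(elements)), elements)
  residuals[free] <- atoms[free] / (beta * b[free]) - 1
  list(p = setNames(res$p, species), lambda = res$lambda,
       atoms = atoms, beta = beta, residuals = residuals,
       elements = elements, b = b)
}

#' Solve gas-phase chemical equilibrium
#'
#' Computes the mass-action equilibrium of an ideal-gas mixture for a given
#' element budget at fixed temperature and total pressure, using an
#' element-potential (Lagrange multiplier) formulation solved by damped
#' Newton iteration in log-abundance variables with temperature continuation;
#' non-convergence triggers up to 5 perturbed restarts before a diagnostic
#' error carrying the element residuals.
#'
#' @param budget an `element_budget` (relative atom abundances)
#' @param T temperature in Kelvin
#' @param P total pressure in bar
#' @param species optional character vector restricting the species set
#'   (default: every gas-phase table species composed of the budget's
#'   elements)
#' @param table thermo table
#' @param hc3n `"eq6"` (default) drives cyanoacetylene with the mass-action
#'   fit of [hc3n_ln_mass_action()]; `"table"` uses the polynomial table
#' @param control solver control overrides (`tol`, `maxit`, `restarts`,
#'   `continuation_steps`, `step_cap`)
#' @return a [gas_state()] whose mixing ratios sum to 1; per-element
#'   conservation residuals are attached as attribute `"residuals"` and the
#'   element potentials (log atom partial pressures) as `"lambda"`
#' @export
solve_gas_equilibrium <- function(budget, T, P, species = NULL,
                                  table = thermo_table(),
                                  hc3n = c("eq6", "table"),
                                  control = list()) {
  hc3n <- match.arg(hc3n)
  sol <- .solve_core(budget, T, P, species, table, clamp = NULL,
                     hc3n = hc3n, control = control)
  gas <- gas_state(sol$p / sum(sol$p), T, P)
  attr(gas, "residuals") <- sol$residuals
  attr(gas, "lambda") <- sol$lambda
  gas
}

#' Equilibrate a gas with graphite condensation
#'
#' Solves the unconstrained gas-phase equilibrium; if the implied carbon
#' monomer partial pressure exceeds the graphite vapor pressure, re-solves
#' with the carbon activity pinned at saturation and assigns the excess
#' carbon to condensed graphite.
#'
#' @inheritParams solve_gas_equilibrium
#' @param variant graphite vapor-pressure variant (see
#'   [graphite_vapor_pressure()])
#' @param vp_coef optional vapor-pressure coefficient override
#' @return object of class `equilibrium_result`: fields `gas` (a
#'   `gas_state`), `graphite_fraction` (fraction of total carbon atoms
#'   condensed), `saturated`, `carbon_activity` (carbon monomer pressure over
#'   the saturation pressure), `residuals`
#' @export
equilibrate_with_graphite <- function(budget, T, P,
                                      variant = c("equilibrium", "kinetics"),
                                      vp_coef = NULL, species = NULL,
                                      table = thermo_table(),
                                      hc3n = c("eq6", "table"),
                                      control = list()) {
  variant <- match.arg(variant)
  hc3n <- match.arg(hc3n)
  pvap <- suppressWarnings(graphite_vapor_pressure(T, variant, coef = vp_coef))
  ab <- budget$abundances
  # The carbon-clamped solve is run first: its gas-phase carbon inventory is
  # the maximum the gas can hold at saturation.  If the input budget carries
  # more carbon than that, the system is saturated and the clamped solution
  # (with the excess assigned to graphite) is the answer; otherwise the
  # unconstrained solve applies.  Doing it in this order avoids asking the
  # gas-only solver for the extreme compositions implied by strongly
  # supersaturated budgets.
  if (("C" %in% names(ab)) && ab[["C"]] > 0 &&
      any(ab[setdiff(names(ab), "C")] > 0)) {
    solc <- .solve_core(budget, T, P, species, table,
                        clamp = c(C = log(pvap)), hc3n = hc3n,
                        control = control)
    refs <- setdiff(solc$elements[solc$b > 0], "C")
    ref <- refs[which.max(solc$b[refs])]
    in_ratio <- ab[["C"]] / ab[[ref]]
    gas_ratio <- solc$atoms[["C"]] / solc$atoms[[ref]]
    if (gas_ratio < in_ratio) {
      gfrac <- max(0, min(1, 1 - gas_ratio / in_ratio))
      gas <- gas_state(solc$p / sum(solc$p), T, P)
      attr(gas, "lambda") <- solc$lambda
      return(structure(list(gas = gas, graphite_fraction = gfrac,
                            saturated = TRUE, carbon_activity = 1,
                            residuals = solc$residuals),
                       class = "equilibrium_result"))
    }
  }
  sol <- .solve_core(budget, T, P, species, table, hc3n = hc3n,
                     control = control)
  pC <- if ("C" %in% names(sol$p)) sol$p[["C"]] else 0
  gas <- gas_state(sol$p / sum(sol$p), T, P)
  attr(gas, "lambda") <- sol$lambda
  structure(list(gas = gas, graphite_fraction = 0, saturated = FALSE,
                 carbon_activity = pC / pvap,
                 residuals = sol$residuals),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("<equilibrium_result> saturated=%s graphite_fraction=%.4f carbon_activity=%.3g\n",
              x$saturated, x$graphite_fraction, x$carbon_activity))
  print(x$gas)
  invisible(x)
}

#' Added-carbon saturation threshold
#'
#' Bisects over the amount of carbon (graphite) added to a base element
#' budget for the smallest addition at which the gas becomes graphite
#' saturated.  The addition parameter is the added-carbon atom fraction of
#' total atoms; the result also reports the total carbon atom fraction at
#' threshold and the added carbon relative to the base budget's initial
#' carbon inventory (the measure in which the threshold for a magmatic gas
#' is ~0.8).
#'
#' @inheritParams equilibrate_with_graphite
#' @param base base `element_budget`, unsaturated at zero addition (an error
#'   is raised otherwise)
#' @param tol bisection tolerance on the added fraction
#' @return list with `added_fraction`, `carbon_fraction_total`,
#'   `added_over_initial_carbon`, and the threshold `equilibrium_result`
#' @export
find_saturation_threshold <- function(base, T, P,
                                      variant = c("equilibrium", "kinetics"),
                                      vp_coef = NULL, tol = 1e-3,
                                      table = thermo_table(),
                                      hc3n = c("eq6", "table"),
                                      control = list()) {
  variant <- match.arg(variant)
  hc3n <- match.arg(hc3n)
  ab <- base$abundances / sum(base$abundances)
  with_added <- function(f) {
    A <- f / (1 - f)          # added C atoms per unit of base atoms
    ab2 <- ab
    ab2[["C"]] <- (if ("C" %in% names(ab2)) ab2[["C"]] else 0) + A
    element_budget(ab2)
  }
  is_sat <- function(f) equilibrate_with_graphite(
    with_added(f), T, P, variant = variant, vp_coef = vp_coef,
    table = table, hc3n = hc3n, control = control)$saturated
  if (is_sat(0))
    stop("base budget is already graphite-saturated at zero addition")
  lo <- 0; hi <- 0.5
  while (!is_sat(hi)) {
    lo <- hi; hi <- (1 + hi) / 2
    if (hi > 1 - 1e-6) stop("no saturation found up to pure-carbon limit")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (is_sat(mid)) hi <- mid else lo <- mid
  }
  f <- hi
  A <- f / (1 - f)
  res <- equilibrate_with_graphite(with_added(f), T, P, variant = variant,
                                   vp_coef = vp_coef, table = table,
                                   hc3n = hc3n, control = control)
  c0 <- if ("C" %in% names(ab)) ab[["C"]] else 0
  list(added_fraction = f,
       carbon_fraction_total = (c0 + A) / (1 + A),
       added_over_initial_carbon = if (c0 > 0) A / c0 else Inf,
       result = res)
}
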