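# Stiff integration of the reversible network ODEs at fixed T and volume,
# with reverse rates enforcing detailed balance and an optional
# zero-dimensional graphite reservoir.

.SOLID_NAME <- "C(s)"

#' Integrate a reaction network
#'
#' Integrates `d[X]/dt = P_X - L_X [X]` for every species at fixed
#' temperature in a closed (constant-volume) parcel initialized from a gas
#' state, using a stiff implicit solver (`deSolve::lsoda`, relative
#' tolerance 1e-8).  Reverse rate constants are derived from the
#' equilibrium constants, so a long enough integration relaxes to
#' thermochemical equilibrium.  With `graphite = TRUE` a zero-dimensional
#' solid-carbon reservoir exchanges with gas-phase atomic carbon at the
#' rates of [graphite_exchange_rates()]: condensation is first order in
#' gas-phase C, evaporation is zero order and switches off when no solid
#' remains, so a sub-saturated gas without graphite experiences no net
#' evaporation.
#'
#' Species of the network absent from the initial state start at a floor of
#' `floor_frac` of the total number density (also the lower clamp applied to
#' the returned states).
#'
#' @param net a `reaction_network`
#' @param initial a [gas_state()] providing the initial mixing ratios and,
#'   unless overridden, `T` and `P`
#' @param T,P temperature (K) and pressure (bar); default to the initial
#'   state's stamps
#' @param t_end integration time in seconds (default one day)
#' @param graphite logical; include gas<->graphite exchange
#' @param graphite_init initial solid carbon, as atoms per cm^3
#' @param vapor_pressure_variant variant used for the exchange rates
#' @param vp_coef optional vapor-pressure coefficient override
#' @param relax_rate graphite exchange condensation rate constant (s^-1)
#' @param rate_target relaxation rate (s^-1) the placeholder-rate
#'   conditioning normalizes each reversible channel to; `NA` integrates the
#'   raw fixture rates
#' @param n_out number of logarithmically spaced output times
#' @param floor_frac concentration floor as a fraction of total density
#' @param rtol,atol solver tolerances (atol in cm^-3)
#' @return object of class `trajectory`: `times` (s), `states` (matrix,
#'   cm^-3, one column per species, plus a `C(s)` column when graphite is
#'   on), `T`, `P`, `species`
#' @export
integrate_network <- function(net, initial, T = initial$T, P = initial$P,
                              t_end = 86400, graphite = FALSE,
                              graphite_init = 0,
                              vapor_pressure_variant = c("kinetics", "equilibrium"),
                              vp_coef = NULL, relax_rate = 100,
                              n_out = 60, floor_frac = 1e-30,
                              rate_target = 100,
                              rtol = 1e-8, atol = 1e-20,
                              table = thermo_table()) {
  vapor_pressure_variant <- match.arg(vapor_pressure_variant)
  species <- net$species
  n_tot <- .number_density(P, T)
  y0 <- setNames(rep(floor_frac * n_tot, length(species)), species)
  known <- intersect(names(initial$mixing_ratios), species)
  y0[known] <- pmax(initial$mixing_ratios[known] * n_tot, floor_frac * n_tot)
  m <- length(net$reactions)
  S <- matrix(0, length(species), m, dimnames = list(species, NULL))
  kf <- numeric(m); kr <- numeric(m)
  react_idx <- vector("list", m); prod_idx <- vector("list", m)
  react_pow <- vector("list", m); prod_pow <- vector("list", m)
  for (i in seq_len(m)) {
    r <- net$reactions[[i]]; st <- r$stoichiometry
    S[names(st$reactants), i] <- S[names(st$reactants), i] - st$reactants
    S[names(st$products), i] <- S[names(st$products), i] + st$products
    kf[i] <- .forward_rate_constant(r, T)
    kr[i] <- if (r$reversible) reverse_rate_constant(r, T, kf[i], table) else 0
    react_idx[[i]] <- match(names(st$reactants), species)
    prod_idx[[i]] <- match(names(st$products), species)
    react_pow[[i]] <- unname(st$reactants)
    prod_pow[[i]] <- unname(st$products)
  }
  use_graphite <- isTRUE(graphite) || net$includes_graphite_exchange
  # Condition the placeholder rates: normalize each reversible reaction's
  # relaxation rate (its equilibrium exchange flux divided by the smallest
  # participating equilibrium pool) onto `rate_target`, scaling kf and kr
  # together so the equilibrium constant (detailed balance, and hence the
  # endpoint) is untouched.  Without this, reverse rates of strongly
  # exergonic reactions reach ~1e20 s^-1 and defeat the stiff corrector,
  # while weak channels freeze for the whole run; the absolute scale of
  # placeholder rates carries no physical meaning (only the endpoint is
  # asserted).  Set `rate_target = NA` to integrate the raw fixture rates.
  if (is.finite(rate_target)) {
    n_eq <- tryCatch({
      x0 <- y0[species] / sum(y0[species])
      budget <- mixing_ratios_to_elements(gas_state(x0, T, P), table)
      if (use_graphite && graphite_init > 0) {
        ab <- budget$abundances
        ab[["C"]] <- (if ("C" %in% names(ab)) ab[["C"]] else 0) +
          graphite_init / n_tot
        budget <- element_budget(ab)
      }
      eqr <- equilibrate_with_graphite(budget, T, P,
                                       variant = vapor_pressure_variant,
                                       vp_coef = vp_coef, species = species,
                                       table = table)
      pmax(eqr$gas$mixing_ratios[species] * n_tot, floor_frac * n_tot)
    }, error = function(e) setNames(rep(n_tot, length(species)), species))
    for (i in seq_len(m)) {
      if (kr[i] <= 0) next
      st <- net$reactions[[i]]$stoichiometry
      phi <- kf[i] * prod(n_eq[names(st$reactants)]^st$reactants)
      parts <- c(names(st$reactants), names(st$products))
      relax <- phi / min(n_eq[parts])
      if (is.finite(relax) && relax > 0) {
        kf[i] <- kf[i] * rate_target / relax
        kr[i] <- kr[i] * rate_target / relax
      }
    }
  }
  if (use_graphite) {
    if (!("C" %in% species))
      stop("graphite exchange needs gas-phase atomic carbon ('C') in the network")
    ex <- graphite_exchange_rates(T, vapor_pressure_variant,
                                  relax_rate = relax_rate, coef = vp_coef)
    n_sat <- unname(ex["evaporation"] / ex["condensation"])
    k_c <- unname(ex["condensation"])
    iC <- match("C", species)
    y0 <- c(y0, setNames(graphite_init, .SOLID_NAME))
  }
  deriv <- function(t, y, parms) {
    n <- pmax(y[seq_along(species)], 0)
    flux <- numeric(m)
    for (i in seq_len(m)) {
      fw <- kf[i] * prod(n[react_idx[[i]]]^react_pow[[i]])
      bw <- if (kr[i] > 0) kr[i] * prod(n[prod_idx[[i]]]^prod_pow[[i]]) else 0
      flux[i] <- fw - bw
    }
    dn <- drop(S %*% flux)
    if (use_graphite) {
      solid <- max(y[length(y)], 0)
      f <- k_c * (n[iC] - n_sat)
      if (f < 0 && solid <= 0) f <- 0     # nothing to evaporate
      dn[iC] <- dn[iC] - f
      dn <- c(dn, f)
    }
    list(dn)
  }
  times <- unique(c(0, 10^seq(log10(max(t_end * 1e-7, 1e-6)), log10(t_end),
                              length.out = n_out)))
  sol <- deSolve::lsoda(y0, times, deriv, parms = NULL, rtol = rtol,
                        atol = atol, maxsteps = 100000)
  if (attr(sol, "istate")[1] < 0)
    warning("integrator reported incomplete convergence; ",
            "returning the last good states")
  states <- pmax(sol[, -1, drop = FALSE], 0)
  colnames(states) <- c(species, if (use_graphite) .SOLID_NAME)
  structure(list(times = sol[, 1], states = states, T = T, P = P,
                 species = species, graphite = use_graphite),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d samples to t=%g s, %d species%s, T=%.1f K\n",
              length(x$times), max(x$times), length(x$species),
              if (x$graphite) " + graphite reservoir" else "", x$T))
  invisible(x)
}

#' Gas mixing ratios at a trajectory sample
#'
#' @param traj a `trajectory`
#' @param i sample index (default: last)
#' @return named mixing-ratio vector over the gas-phase species
#' @export
trajectory_mixing_ratios <- function(traj, i = length(traj$times)) {
  n <- traj$states[i, traj$species]
  n / sum(n)
}

#' Per-element atom totals along a trajectory
#'
#' Includes the condensed carbon reservoir, so the totals are conserved
#' quantities of the integration.
#'
#' @param traj a `trajectory`
#' @param table thermo table
#' @return matrix (time x element) of atom densities in cm^-3
#' @export
trajectory_element_totals <- function(traj, table = thermo_table()) {
  elements <- sort(unique(unlist(lapply(traj$species, function(s)
    names(.get_species(table, s)$composition)))))
  out <- matrix(0, length(traj$times), length(elements),
                dimnames = list(NULL, elements))
  for (s in traj$species) {
    comp <- .get_species(table, s)$composition
    for (el in names(comp))
      out[, el] <- out[, el] + comp[[el]] * traj$states[, s]
  }
  if (traj$graphite) out[, "C"] <- out[, "C"] + traj$states[, .SOLID_NAME]
  out
}

#' First time a trajectory reaches a reference composition
#'
#' Scans the sampled states for the first time at which the maximum relative
#' deviation of the gas mixing ratios from `reference` falls below `tol`,
#' over species whose reference ratio exceeds `floor`.  Returns `Inf` (the
#' not-converged sentinel) if no sample qualifies.
#'
#' @param traj a `trajectory`
#' @param reference a [gas_state()] or named mixing-ratio vector
#' @param tol maximum relative deviation
#' @param floor reference mixing ratio below which species are ignored
#' @return time in seconds, or `Inf`
#' @export
time_to_equilibrium <- function(traj, reference, tol = 1e-2, floor = 1e-10) {
  ref <- if (inherits(reference, "gas_state")) reference$mixing_ratios
         else reference
  keep <- names(ref)[ref > floor]
  keep <- intersect(keep, traj$species)
  for (i in seq_along(traj$times)) {
    x <- trajectory_mixing_ratios(traj, i)
    dev <- max(abs(x[keep] - ref[keep]) / ref[keep])
    if (dev < tol) return(traj$times[i])
  }
  Inf
}
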