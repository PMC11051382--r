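# Brute-force Gibbs-minimization equilibrium, independent of the Newton
# element-potential solver.  Used as the reference oracle for small systems
# and for the packaged toy-network fixtures.

#' Brute-force equilibrium by dense-grid Gibbs minimization
#'
#' Minimizes the total dimensionless Gibbs free energy
#' `G/RT = sum_i n_i (g_i + ln P + ln(n_i/n_tot))` (gas; condensed species
#' contribute `n_i g_i`) over the reaction extents of a spanning reaction
#' set, by exhaustive search on a dense grid with iterative refinement.
#' Element conservation is exact by construction (compositions move only
#' along reaction vectors).  Intended for small systems (<= ~8 species,
#' <= 3 independent reactions); it is deliberately independent of the
#' element-potential solver so the two can cross-check each other.
#'
#' @param moles0 named vector of initial moles per species
#' @param reactions list of [reaction_stoichiometry()] spanning the
#'   stoichiometric space to search
#' @param T temperature (K)
#' @param P pressure (bar)
#' @param table thermo table
#' @param n grid points per reaction extent per refinement pass
#' @param passes refinement passes (each zooms by ~n/4)
#' @param hc3n as in [solve_gas_equilibrium()]
#' @param constant `"P"` minimizes Gibbs energy at fixed total pressure `P`;
#'   `"V"` minimizes the Helmholtz-type potential of a closed
#'   constant-volume parcel whose initial total pressure is `P` (matching a
#'   constant-volume kinetic integration, where the pressure drifts as mole
#'   numbers change)
#' @return list with `moles`, `mixing_ratios` (gas phase), `G_rt`
#' @export
gibbs_grid_equilibrium <- function(moles0, reactions, T, P,
                                   table = thermo_table(), n = 21,
                                   passes = 8, hc3n = "eq6",
                                   constant = c("P", "V")) {
  constant <- match.arg(constant)
  species <- names(moles0)
  for (r in reactions) .check_balanced(r, table)
  g <- vapply(species, function(s) {
    if (identical(s, "HC3N") && identical(hc3n, "eq6")) {
      comp <- .get_species(table, s)$composition
      g_at <- vapply(names(comp), function(el)
        .species_g_rt(.get_species(table, el), T), numeric(1))
      return(sum(g_at * comp) - hc3n_ln_mass_action(T))
    }
    .species_g_rt(.get_species(table, s), T)
  }, numeric(1))
  is_gas <- vapply(species, function(s)
    .get_species(table, s)$phase == "gas", logical(1))
  vecs <- vapply(reactions, function(r) {
    v <- setNames(numeric(length(species)), species)
    v[names(r$reactants)] <- v[names(r$reactants)] - r$reactants
    v[names(r$products)] <- v[names(r$products)] + r$products
    v
  }, setNames(numeric(length(species)), species))
  nr <- length(reactions)
  n <- max(7L, min(n, floor(2e5^(1 / nr))))   # keep the grid desk-scale
  vscale <- P / sum(moles0[is_gas])   # bar per mole unit at constant volume
  gibbs <- function(nm) {
    ng <- nm[is_gas]
    terms <- if (constant == "P") {
      nt <- sum(ng)
      ifelse(ng > 0, ng * (g[is_gas] + log(P) + log(ng / nt)), 0)
    } else {
      ifelse(ng > 0, ng * (g[is_gas] + log(ng * vscale) - 1), 0)
    }
    sum(terms) + sum(nm[!is_gas] * g[!is_gas])
  }
  # extent bounds from non-negativity along each direction separately
  centre <- rep(0, nr)
  half <- vapply(seq_len(nr), function(k) {
    v <- vecs[, k]
    pos <- v > 0; neg <- v < 0
    up <- if (any(neg)) min(-moles0[neg] / v[neg]) else sum(moles0)
    dn <- if (any(pos)) max(-moles0[pos] / v[pos]) else -sum(moles0)
    max(abs(up), abs(dn))
  }, numeric(1))
  half0 <- half
  best <- list(xi = centre, G = Inf)
  for (pass in seq_len(passes)) {
    grids <- lapply(seq_len(nr), function(k)
      seq(best$xi[k] - half[k], best$xi[k] + half[k], length.out = n))
    pts <- as.matrix(expand.grid(grids))
    for (i in seq_len(nrow(pts))) {
      nm <- moles0 + drop(vecs %*% pts[i, ])
      if (any(nm < -1e-12)) next
      nm <- pmax(nm, 0)
      Gv <- gibbs(nm)
      if (is.finite(Gv) && Gv < best$G) best <- list(xi = pts[i, ], G = Gv)
    }
    half <- half * (4 / (n - 1)) * 2   # zoom around the best point
  }
  # simplex polish: narrow curved valleys (and minima hugging the
  # non-negativity boundary, where trace species go to ~0) defeat
  # axis-aligned grids; Nelder-Mead on the extents finishes the job without
  # touching the element-potential machinery being checked
  objective <- function(xi) {
    nm <- moles0 + drop(vecs %*% xi)
    if (any(nm < 0)) return(1e10)
    gibbs(nm)
  }
  gradient <- function(xi) {
    nm <- pmax(moles0 + drop(vecs %*% xi), 1e-300)
    mu <- if (constant == "P") {
      nt <- sum(nm[is_gas])
      ifelse(is_gas, g + log(P) + log(nm / nt), g)
    } else {
      ifelse(is_gas, g + log(nm * vscale), g)
    }
    drop(crossprod(vecs, mu))
  }
  opt <- if (nr == 1L) {
    stats::optim(best$xi, objective, method = "Brent",
                 lower = best$xi - half0, upper = best$xi + half0)
  } else {
    stats::optim(best$xi, objective, method = "Nelder-Mead",
                 control = list(maxit = 20000, reltol = 1e-14))
  }
  if (is.finite(opt$value) && opt$value < best$G)
    best <- list(xi = opt$par, G = opt$value)
  # Zero the reaction affinities (the gradient components) by a damped
  # Newton iteration in extent space with a finite-difference Jacobian.
  # This resolves trace species to relative precision that function-value
  # searches cannot; the grid stage guarantees the right basin.
  xi <- best$xi
  feasible <- function(xi) all(moles0 + drop(vecs %*% xi) > 0)
  for (it in 1:80) {
    A <- gradient(xi)
    if (max(abs(A)) < 1e-12) break
    h <- pmax(abs(xi), max(half0)) * 1e-7
    J <- vapply(seq_len(nr), function(k) {
      e <- replace(numeric(nr), k, h[k])
      (gradient(xi + e) - gradient(xi - e)) / (2 * h[k])
    }, numeric(nr))
    dxi <- tryCatch(solve(J, -A), error = function(e) NULL)
    if (is.null(dxi)) break
    step <- 1
    repeat {
      xi2 <- xi + step * dxi
      if (feasible(xi2) && max(abs(gradient(xi2))) < max(abs(A))) {
        xi <- xi2; break
      }
      step <- step / 2
      if (step < 1e-12) break
    }
    if (step < 1e-12) break
  }
  if (feasible(xi) && objective(xi) <= best$G + 1e-9)
    best <- list(xi = xi, G = objective(xi))
  moles <- pmax(moles0 + drop(vecs %*% best$xi), 0)
  mr <- moles[is_gas] / sum(moles[is_gas])
  list(moles = moles, mixing_ratios = mr, G_rt = best$G)
}
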