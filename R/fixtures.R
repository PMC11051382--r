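# Synthetic fixtures: the printed initial gas, seeded random element budgets,
# and random reversible toy networks with independently computed equilibria.

# evaluate expr under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

#' Fixture generation spec
#'
#' @param seed integer seed; identical specs yield bit-identical fixtures
#' @param n_species species count cap for toy networks (<= 8; the reference
#'   oracle is brute force)
#' @param element_palette elements the fixture may draw on
#' @param rate_scale characteristic forward rate scale (s^-1 or cm^3 s^-1
#'   according to reaction order)
#' @return object of class `fixture_spec`
#' @export
fixture_spec <- function(seed = 1L, n_species = 6L,
                         element_palette = c("H", "C", "N", "O"),
                         rate_scale = 1e-10) {
  stopifnot(n_species >= 2L, n_species <= 8L)
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 element_palette = element_palette, rate_scale = rate_scale,
                 rng = "Mersenne-Twister (R default)", version = "1.0"),
            class = "fixture_spec")
}

#' The printed initial magmatic gas composition
#'
#' Mixing ratios of the fiducial 1700 degC, 100 bar, QFM-1 magmatic gas with
#' 5.7% N2: CO 0.35, H2 0.1, N2 0.057, O2 7.6e-10, CH4 1.4e-6, CO2 0.23,
#' H2O 0.26.  The printed ratios sum to 0.997 (rounding); the residual 0.003
#' is assigned proportionally across the printed species so the state
#' normalizes exactly.
#'
#' @return a [gas_state()] at 1973.15 K, 100 bar
#' @export
table1_gas <- function() {
  x <- c(CO = 0.35, H2 = 0.1, N2 = 0.057, O2 = 7.6e-10, CH4 = 1.4e-6,
         CO2 = 0.23, H2O = 0.26)
  gas_state(x / sum(x), T = 1973.15, P = 100)
}

#' Seeded random element budget
#'
#' Element abundances drawn log-uniformly over `range` for each palette
#' element; identical specs give identical budgets.
#'
#' @param spec a [fixture_spec()]
#' @param range log-uniform bounds of the relative abundances
#' @return an [element_budget()]
#' @export
random_budget <- function(spec = fixture_spec(), range = c(1e-2, 1)) {
  ab <- .with_seed(spec$seed, {
    10^stats::runif(length(spec$element_palette),
                    log10(range[1]), log10(range[2]))
  })
  names(ab) <- spec$element_palette
  out <- element_budget(ab)
  attr(out, "manifest") <- list(rng = spec$rng, version = spec$version,
                                seed = spec$seed, range = range)
  out
}

# curated pool of element-balanced reversible reactions over the packaged
# table, from which toy networks are sampled
.TOY_REACTION_POOL <- list(
  list(r = c(H = 2), p = c(H2 = 1)),
  list(r = c(O = 2), p = c(O2 = 1)),
  list(r = c(N = 2), p = c(N2 = 1)),
  list(r = c(H2 = 1, O = 1), p = c(OH = 1, H = 1)),
  list(r = c(OH = 1, H2 = 1), p = c(H2O = 1, H = 1)),
  list(r = c(O2 = 1, H = 1), p = c(OH = 1, O = 1)),
  list(r = c(CO = 1, OH = 1), p = c(CO2 = 1, H = 1)),
  list(r = c(C = 1, O2 = 1), p = c(CO = 1, O = 1)),
  list(r = c(CH4 = 1, H = 1), p = c(CH3 = 1, H2 = 1)),
  list(r = c(CN = 1, H2 = 1), p = c(HCN = 1, H = 1)),
  list(r = c(HCN = 1), p = c(HNC = 1)),
  list(r = c(C = 1, N = 1), p = c(CN = 1)),
  list(r = c(C2H2 = 1, H2 = 1), p = c(C2H4 = 1)),
  list(r = c(C2H4 = 1, H2 = 1), p = c(C2H6 = 1)),
  list(r = c(CO = 1, H2 = 1), p = c(H2CO = 1)),
  list(r = c(CO = 1, H = 1), p = c(HCO = 1)),
  list(r = c(NH = 1, H2 = 1), p = c(NH3 = 1)),
  list(r = c(N = 1, H = 1), p = c(NH = 1)))

#' Random reversible toy network with reference equilibrium
#'
#' Samples element-balanced reversible reactions from a curated pool until
#' the induced species set reaches the spec's size cap, assigns log-uniform
#' forward rate constants around `rate_scale`, draws a random initial
#' composition, and computes the network's equilibrium with the independent
#' dense-grid Gibbs-minimization oracle ([gibbs_grid_equilibrium()]).  Used
#' to verify that kinetic integration endpoints relax to thermochemical
#' equilibrium.
#'
#' @param spec a [fixture_spec()]
#' @param T temperature (K)
#' @param P pressure (bar)
#' @param table thermo table
#' @return list with `network` (a parsed reversible network), `initial` (a
#'   `gas_state`), `reference` (oracle equilibrium mixing ratios), `T`, `P`
#' @export
toy_network <- function(spec = fixture_spec(), T = 1973.15, P = 100,
                        table = thermo_table()) {
  out <- .with_seed(spec$seed, {
    pool <- sample(.TOY_REACTION_POOL)
    chosen <- list(); sp <- character(0)
    for (cand in pool) {
      if (length(chosen) >= 3L) break    # keeps the oracle's grid tractable
      newsp <- union(sp, c(names(cand$r), names(cand$p)))
      if (length(newsp) <= spec$n_species) {
        chosen <- c(chosen, list(cand)); sp <- newsp
      }
    }
    rates <- 10^stats::runif(length(chosen), log10(spec$rate_scale) - 1,
                             log10(spec$rate_scale) + 1)
    moles0 <- stats::runif(length(sp), 0.05, 1)
    names(moles0) <- sp
    list(chosen = chosen, rates = rates, moles0 = moles0, sp = sp)
  })
  rxns <- lapply(seq_along(out$chosen), function(i)
    reaction(reaction_stoichiometry(out$chosen[[i]]$r, out$chosen[[i]]$p),
             A = out$rates[i], n = 0, Ea = 0, reversible = TRUE))
  net <- reaction_network(rxns, table = table)
  stoich <- lapply(out$chosen, function(cand)
    reaction_stoichiometry(cand$r, cand$p))
  ref <- gibbs_grid_equilibrium(out$moles0, stoich, T, P, table = table,
                                constant = "V")
  res <- list(network = net,
              initial = gas_state(out$moles0 / sum(out$moles0), T, P),
              reference = ref$mixing_ratios, T = T, P = P, spec = spec)
  class(res) <- "toy_network"
  res
}
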