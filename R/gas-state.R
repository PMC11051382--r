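#' Element budget
#'
#' Relative atom abundances of the elements in play (H, C, N, O by default;
#' extensible).  Only ratios matter; the budget need not be normalized.
#'
#' @param abundances named non-negative numeric vector, e.g.
#'   `c(H = 0.72, C = 0.58, N = 0.114, O = 1.07)`
#' @return object of class `element_budget`
#' @export
element_budget <- function(abundances) {
  if (is.null(names(abundances)) || any(names(abundances) == ""))
    stop("element abundances must be named")
  if (any(abundances < 0)) stop("element abundances must be non-negative")
  if (sum(abundances) <= 0) stop("element budget is empty (sum must be > 0)")
  structure(list(abundances = abundances), class = "element_budget")
}

#' @export
print.element_budget <- function(x, ...) {
  a <- x$abundances / sum(x$abundances)
  cat("<element_budget> ",
      paste(sprintf("%s=%.4g", names(a), a), collapse = " "),
      " (normalized)\n", sep = "")
  invisible(x)
}

#' Gas state
#'
#' A temperature/pressure-stamped vector of gas mixing ratios (mole
#' fractions).  Ratios must be non-negative and sum to 1 within 1e-9.
#'
#' @param mixing_ratios named non-negative numeric vector summing to 1
#' @param T temperature in Kelvin
#' @param P total pressure in bar
#' @return object of class `gas_state`
#' @export
gas_state <- function(mixing_ratios, T, P) {
  if (is.null(names(mixing_ratios))) stop("mixing ratios must be named")
  if (any(mixing_ratios < 0)) stop("mixing ratios must be non-negative")
  if (abs(sum(mixing_ratios) - 1) > 1e-9)
    stop(sprintf("mixing ratios must sum to 1 (got %.12f)", sum(mixing_ratios)))
  structure(list(mixing_ratios = mixing_ratios, T = T, P = P),
            class = "gas_state")
}

#' @export
print.gas_state <- function(x, n = 8, ...) {
  cat(sprintf("<gas_state> T = %.2f K, P = %g bar, %d species\n",
              x$T, x$P, length(x$mixing_ratios)))
  top <- sort(x$mixing_ratios, decreasing = TRUE)
  top <- top[seq_len(min(n, length(top)))]
  for (i in seq_along(top))
    cat(sprintf("  %-7s %.4e\n", names(top)[i], top[i]))
  invisible(x)
}

#' Element budget of a gas mixture
#'
#' Per-element atom counts per gas molecule, summed over species weighted by
#' mixing ratio.  Bridges a printed gas composition to the equilibrium
#' solver's elemental representation.
#'
#' @param gas a `gas_state`
#' @param table thermo table used to resolve species compositions
#' @return an `element_budget` (unnormalized atoms per gas molecule)
#' @export
mixing_ratios_to_elements <- function(gas, table = thermo_table()) {
  x <- gas$mixing_ratios
  if (length(x) == 0L || sum(x) <= 0) stop("empty gas state")
  out <- numeric(0)
  for (sp in names(x)) {
    comp <- .get_species(table, sp)$composition
    for (el in names(comp)) {
      out[el] <- (if (is.na(out[el])) 0 else out[el]) + x[[sp]] * comp[[el]]
    }
  }
  element_budget(out[!is.na(out)])
}
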