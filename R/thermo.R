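#' Parse an elemental formula string
#'
#' Formulas are written as space-separated `element:count` pairs, e.g.
#' `"C:1 H:4"` for methane.
#'
#' @param x formula string
#' @return named integer vector of atom counts
#' @keywords internal
parse_formula <- function(x) {
  parts <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  m <- regmatches(parts, regexec("^([A-Za-z][a-z]?):([0-9]+)$", parts))
  if (any(lengths(m) != 3L)) {
    stop("malformed formula: '", x, "'", call. = FALSE)
  }
  counts <- vapply(m, function(g) as.integer(g[3]), integer(1))
  names(counts) <- vapply(m, `[`, character(1), 2)
  if (any(counts <= 0L)) stop("formula atom counts must be positive: '", x, "'")
  counts
}

#' Construct a thermochemical species record
#'
#' A species carries its elemental composition, phase, and one NASA-7
#' polynomial coefficient set per temperature range.  The coefficient ranges
#' must be contiguous and non-overlapping; evaluating outside their union is
#' an error.
#'
#' @param name species identifier
#' @param composition named integer vector of atom counts (all positive)
#' @param phase `"gas"` or `"solid"`
#' @param coeffs data frame with columns `T_low`, `T_high`, `a1`..`a7`
#' @param mass molar mass in g/mol (optional, for bookkeeping)
#' @param source_note free-text provenance
#' @return object of class `thermo_species`
#' @export
thermo_species <- function(name, composition, phase = c("gas", "solid"),
                           coeffs, mass = NA_real_, source_note = "") {
  phase <- match.arg(phase)
  composition <- composition[order(names(composition))]
  if (length(composition) == 0L || any(composition <= 0))
    stop("composition must be non-empty with positive counts: ", name)
  coeffs <- coeffs[order(coeffs$T_low), , drop = FALSE]
  if (nrow(coeffs) > 1L &&
      any(abs(coeffs$T_high[-nrow(coeffs)] - coeffs$T_low[-1L]) > 1e-9))
    stop("coefficient temperature ranges must be contiguous: ", name)
  if (any(coeffs$T_high <= coeffs$T_low))
    stop("empty coefficient temperature range: ", name)
  structure(list(name = name, composition = composition, phase = phase,
                 coeffs = coeffs, mass = mass, source_note = source_note),
            class = "thermo_species")
}

#' @export
print.thermo_species <- function(x, ...) {
  cat("<thermo_species> ", x$name, " [", x$phase, "] ",
      paste0(names(x$composition), x$composition, collapse = ""),
      "  ranges: ", min(x$coeffs$T_low), "-", max(x$coeffs$T_high), " K\n",
      sep = "")
  invisible(x)
}

#' Read a NASA-7 thermochemical table from CSV
#'
#' One row per coefficient range, columns `name`, `formula`, `phase`, `mass`,
#' `T_low`, `T_high`, `a1`..`a7`, `source_note`.  `#` lines are comments; the
#' header comment carries the table version.
#'
#' @param path CSV file path
#' @return object of class `thermo_table`
#' @seealso [thermo_table()] for the packaged default table
#' @export
read_thermo_table <- function(path) {
  first <- readLines(path, n = 1L)
  version <- if (startsWith(first, "#")) sub("^#\\s*", "", first) else "unversioned"
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "formula", "phase", "T_low", "T_high", paste0("a", 1:7))
  if (!all(need %in% names(df)))
    stop("thermo table is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  species <- lapply(split(df, df$name), function(rows) {
    thermo_species(rows$name[1], parse_formula(rows$formula[1]),
                   phase = rows$phase[1],
                   coeffs = rows[, c("T_low", "T_high", paste0("a", 1:7))],
                   mass = if ("mass" %in% names(rows)) rows$mass[1] else NA_real_,
                   source_note = if ("source_note" %in% names(rows))
                     rows$source_note[1] else "")
  })
  structure(list(species = species, version = version), class = "thermo_table")
}

#' The packaged H/C/N/O thermochemical table
#'
#' NASA-7 polynomials for ~34 gas-phase H/C/N/O species plus graphite,
#' generated once from rigid-rotor/harmonic-oscillator statistical mechanics
#' over curated spectroscopic constants and reference formation enthalpies
#' (see the table's `source_note` column), and shipped as a versioned CSV in
#' `inst/extdata`.  The table is cached for the session.
#'
#' @return a `thermo_table`
#' @export
thermo_table <- function() {
  if (is.null(.ventgas_cache$thermo)) {
    path <- system.file("extdata", "thermo_hcno.csv", package = "ventgas",
                        mustWork = TRUE)
    .ventgas_cache$thermo <- read_thermo_table(path)
  }
  .ventgas_cache$thermo
}

#' @export
print.thermo_table <- function(x, ...) {
  cat("<thermo_table> ", length(x$species), " species (",
      sum(vapply(x$species, function(s) s$phase == "gas", logical(1))),
      " gas), version: ", x$version, "\n", sep = "")
  invisible(x)
}

#' Write the JSON mirror of a thermo table
#'
#' @param table a `thermo_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_thermo_json <- function(table, path) {
  obj <- list(version = table$version,
              species = lapply(table$species, function(s)
                list(name = s$name, composition = as.list(s$composition),
                     phase = s$phase, mass = s$mass,
                     coeff_sets = s$coeffs, source_note = s$source_note)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.get_species <- function(table, name) {
  s <- table$species[[name]]
  if (is.null(s)) stop("species not in thermo table: ", name, call. = FALSE)
  s
}

# Raw dimensionless Gibbs energy g = G/RT from the NASA-7 form, in the
# convention H(298.15 K) = dHf(298.15 K).  Scalar T.
.species_g_rt <- function(species, T) {
  cf <- species$coeffs
  row <- which(T >= cf$T_low & T <= cf$T_high)[1]
  if (is.na(row))
    stop(sprintf("T = %.6g K outside coefficient ranges [%g, %g] for species %s",
                 T, min(cf$T_low), max(cf$T_high), species$name), call. = FALSE)
  a <- as.numeric(cf[row, paste0("a", 1:7)])
  h_rt <- a[1] + a[2] / 2 * T + a[3] / 3 * T^2 + a[4] / 4 * T^3 +
    a[5] / 5 * T^4 + a[6] / T
  s_r <- a[1] * log(T) + a[2] * T + a[3] / 2 * T^2 + a[4] / 3 * T^3 +
    a[5] / 4 * T^4 + a[7]
  h_rt - s_r
}

# g = G/RT for several species at one T; returns named vector
.g_rt <- function(table, names, T) {
  vapply(names, function(n) .species_g_rt(.get_species(table, n), T), numeric(1))
}

# reference-state species per element (gas-phase standard elements; graphite
# for carbon), as (species name, atoms of the element per molecule)
.REFERENCE_STATES <- list(H = c("H2", 2), C = c("C(s)", 1),
                          N = c("N2", 2), O = c("O2", 2))

#' Dimensionless Gibbs free energy of formation
#'
#' Evaluates the NASA-7 polynomials for a species and subtracts the
#' stoichiometric free energies of the reference-state elements (H2, N2, O2
#' gas; graphite for carbon), returning the formation Gibbs energy divided by
#' RT.  For a reference element itself the result is ~0 at 298.15 K by
#' construction.
#'
#' @param species a `thermo_species`, or a species name resolved in `table`
#' @param T temperature in Kelvin (scalar); must lie inside the species'
#'   coefficient ranges, otherwise an error naming the species is raised
#' @param table thermo table used to resolve names and reference elements
#' @return dGf/RT (dimensionless)
#' @export
gibbs_of_formation <- function(species, T, table = thermo_table()) {
  if (is.character(species)) species <- .get_species(table, species)
  g <- .species_g_rt(species, T)
  for (el in names(species$composition)) {
    ref <- .REFERENCE_STATES[[el]]
    if (is.null(ref)) stop("no reference state defined for element ", el)
    g <- g - species$composition[[el]] *
      .species_g_rt(.get_species(table, ref[1]), T) / as.numeric(ref[2])
  }
  unname(g)
}

#' Reaction stoichiometry
#'
#' @param reactants,products named numeric vectors of positive stoichiometric
#'   coefficients (species name -> coefficient)
#' @return object of class `reaction_stoichiometry`
#' @export
reaction_stoichiometry <- function(reactants, products) {
  if (any(reactants <= 0) || any(products <= 0))
    stop("stoichiometric coefficients must be positive")
  both <- intersect(names(reactants), names(products))
  if (length(both) > 0L)
    stop("species on both sides of the reaction: ",
         paste(both, collapse = ", "))
  structure(list(reactants = reactants, products = products),
            class = "reaction_stoichiometry")
}

#' @export
format.reaction_stoichiometry <- function(x, ...) {
  side <- function(v) paste(ifelse(v == 1, names(v),
                                   paste(v, names(v))), collapse = " + ")
  paste(side(x$reactants), "<=>", side(x$products))
}

#' @export
print.reaction_stoichiometry <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# net atom change of a reaction per element (zero vector iff balanced)
.element_imbalance <- function(rxn, table) {
  tally <- function(v, sign) {
    out <- numeric(0)
    for (n in names(v)) {
      comp <- .get_species(table, n)$composition
      for (el in names(comp)) {
        out[el] <- (if (is.na(out[el])) 0 else out[el]) +
          sign * v[[n]] * comp[[el]]
      }
    }
    out
  }
  r <- tally(rxn$reactants, -1)
  p <- tally(rxn$products, +1)
  for (el in names(p)) r[el] <- (if (is.na(r[el])) 0 else r[el]) + p[el]
  r[!is.na(r)]
}

.check_balanced <- function(rxn, table) {
  imb <- .element_imbalance(rxn, table)
  if (any(abs(imb) > 1e-9))
    stop("reaction is not element-balanced (", format(rxn), "): ",
         paste(names(imb)[abs(imb) > 1e-9], collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Gibbs free energy change of a reaction
#'
#' Sum of product formation free energies minus reactants, at 1 bar standard
#' state.
#'
#' @param rxn a `reaction_stoichiometry`
#' @param table thermo table
#' @param T temperature (K)
#' @return dGr in kJ/mol
#' @export
reaction_delta_g <- function(rxn, table = thermo_table(), T) {
  .check_balanced(rxn, table)
  g <- 0
  for (n in names(rxn$products)) g <- g + rxn$products[[n]] *
      .species_g_rt(.get_species(table, n), T)
  for (n in names(rxn$reactants)) g <- g - rxn$reactants[[n]] *
      .species_g_rt(.get_species(table, n), T)
  unname(g * .RGAS * T / 1e3)
}

#' Equilibrium constant of a reaction
#'
#' `exp(-dGr/RT)` with activities referenced to the 1 bar standard state
#' (graphite activity 1 when present).
#'
#' @inheritParams reaction_delta_g
#' @return dimensionless Keq
#' @export
equilibrium_constant <- function(rxn, table = thermo_table(), T) {
  exp(-reaction_delta_g(rxn, table, T) * 1e3 / (.RGAS * T))
}

#' Cyanoacetylene mass-action constant
#'
#' ln K(T) for the formation of HC3N from gaseous atoms (H + 3C + N), in the
#' five-term fit form used by equilibrium atmosphere codes, with pressures in
#' bar.  This fit can drive HC3N in the equilibrium solver in place of the
#' polynomial table (see the `hc3n` argument of [solve_gas_equilibrium()]).
#'
#' @param T temperature in Kelvin (vectorized); must be positive
#' @return ln K (dimensionless)
#' @export
hc3n_ln_mass_action <- function(T) {
  if (any(T <= 0)) stop("temperature must be positive")
  2.96e5 / T - 4.83 * log(T) - 28.47 + 1.91e-3 * T - 1.10e-7 * T^2
}

#' Default graphite vapor-pressure coefficients
#'
#' Both fits have the form `log10 p[bar] = a - b/T - c*T^2 - d/T^2`.  The
#' `kinetics` and `equilibrium` variants differ in their leading terms; the
#' equilibrium variant reproduces the saturation pressure implied by the
#' packaged graphite free energies to within a few percent, while the
#' kinetics variant sits a factor of ~4 above it at magmatic temperatures --
#' that offset is what separates the kinetics and equilibrium branches of the
#' graphite-addition sweeps.
#'
#' @param variant `"kinetics"` or `"equilibrium"`
#' @return named numeric vector `c(a, b, c, d)`
#' @export
vapor_pressure_coefficients <- function(variant = c("kinetics", "equilibrium")) {
  variant <- match.arg(variant)
  switch(variant,
         kinetics    = c(a = 6.455, b = 2.7709e4, c = 0, d = 1e7),
         equilibrium = c(a = 4.855, b = 2.5709e4, c = 0, d = 1e7))
}

#' Graphite vapor pressure
#'
#' Saturation vapor pressure of carbon monomer over graphite,
#' `10^(a - b/T - c*T^2 - d/T^2)` bar.  The fit is intended for 1000-4500 K;
#' outside that window the value is still returned but carries a
#' `"vp_extrapolated"` attribute and a warning.
#'
#' @param T temperature in Kelvin (vectorized)
#' @param variant which coefficient set to use (the kinetics and equilibrium
#'   models of the parent study used different fits)
#' @param coef optional override of the coefficients, as `c(a, b, c, d)`
#' @return vapor pressure in bar
#' @export
graphite_vapor_pressure <- function(T, variant = c("kinetics", "equilibrium"),
                                    coef = NULL) {
  if (is.null(coef)) coef <- vapor_pressure_coefficients(match.arg(variant))
  p <- 10^(coef[["a"]] - coef[["b"]] / T - coef[["c"]] * T^2 - coef[["d"]] / T^2)
  out_of_window <- T < 1000 | T > 4500
  if (any(out_of_window)) {
    warning("graphite vapor pressure evaluated outside its 1000-4500 K window")
    attr(p, "vp_extrapolated") <- out_of_window
  }
  p
}
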