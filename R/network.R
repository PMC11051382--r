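# Reversible reaction networks: construction, the plain-text reaction-list
# dialect, and detailed-balance reverse rates.

#' A reaction with a forward rate law
#'
#' Forward rate constants follow the modified Arrhenius form
#' `k(T) = A * T^n * exp(-Ea/T)` with `Ea` in Kelvin and `A` in the cgs
#' units implied by the reaction order (s^-1, cm^3 s^-1, cm^6 s^-1, ...).
#' Reverse rate constants are never stored: they are derived from the
#' equilibrium constant at run time so that detailed balance holds exactly
#' (see [reverse_rate_constant()]).
#'
#' @param stoichiometry a [reaction_stoichiometry()]
#' @param A,n,Ea modified-Arrhenius parameters (`Ea` in K)
#' @param reversible logical
#' @return object of class `reaction`
#' @export
reaction <- function(stoichiometry, A, n = 0, Ea = 0, reversible = TRUE) {
  if (A < 0) stop("forward rate prefactor must be non-negative")
  structure(list(stoichiometry = stoichiometry, A = A, n = n, Ea = Ea,
                 reversible = reversible), class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  arrow <- if (x$reversible) "<=>" else "->"
  s <- sub("<=>", arrow, format(x$stoichiometry), fixed = TRUE)
  cat(sprintf("%s ; A=%g n=%g Ea=%g\n", s, x$A, x$n, x$Ea))
  invisible(x)
}

.forward_rate_constant <- function(rxn, T) rxn$A * T^rxn$n * exp(-rxn$Ea / T)

.canonical_rxn_key <- function(st) {
  side <- function(v) paste(sort(paste0(v, "*", names(v))), collapse = "+")
  paste(side(st$reactants), side(st$products), sep = ">")
}

#' A validated reaction network
#'
#' @param reactions list of [reaction()] objects
#' @param table thermo table; every species must resolve here and every
#'   reaction must be element-balanced
#' @param includes_graphite_exchange whether gas<->graphite exchange is part
#'   of the network when integrated
#' @return object of class `reaction_network` with the derived species set
#' @export
reaction_network <- function(reactions, table = thermo_table(),
                             includes_graphite_exchange = FALSE) {
  keys <- character(0)
  for (i in seq_along(reactions)) {
    st <- reactions[[i]]$stoichiometry
    .check_balanced(st, table)
    key <- .canonical_rxn_key(st)
    if (key %in% keys) stop("duplicate reaction: ", format(st))
    keys <- c(keys, key)
  }
  species <- sort(unique(unlist(lapply(reactions, function(r)
    c(names(r$stoichiometry$reactants), names(r$stoichiometry$products))))))
  structure(list(reactions = reactions, species = species,
                 includes_graphite_exchange = includes_graphite_exchange),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d reactions, %d species%s\n",
              length(x$reactions), length(x$species),
              if (x$includes_graphite_exchange) " (+ graphite exchange)" else ""))
  invisible(x)
}

.parse_side <- function(txt, lineno) {
  terms <- strsplit(txt, "\\+")[[1]]
  out <- numeric(0)
  for (tm in terms) {
    tm <- trimws(tm)
    m <- regmatches(tm, regexec("^([0-9]+)?\\s*([A-Za-z][A-Za-z0-9()]*)$", tm))[[1]]
    if (length(m) != 3L)
      stop("line ", lineno, ": cannot parse species term '", tm, "'",
           call. = FALSE)
    coef <- if (m[2] == "") 1 else as.numeric(m[2])
    sp <- m[3]
    out[sp] <- (if (is.na(out[sp])) 0 else out[sp]) + coef
  }
  out[!is.na(out)]
}

#' Parse a reaction-list text into a network
#'
#' The dialect is one reaction per line:
#' `R1 + R2 <=> P1 + P2 ; A=<val> n=<val> Ea=<val>`
#' with `->` for irreversible reactions, optional leading integer
#' stoichiometric coefficients (`2 H <=> H2`), and `#` comment lines.  A
#' fixture header (comment lines `# species: <n>` / `# reactions: <n>`)
#' describing the file is preserved in the returned network's
#' `header` attribute.  Element-unbalanced lines are rejected with their
#' line number.
#'
#' @param text character vector of lines, or a single string with newlines
#' @param table thermo table for validation
#' @param includes_graphite_exchange passed through to [reaction_network()]
#' @return a `reaction_network`
#' @export
parse_network <- function(text, table = thermo_table(),
                          includes_graphite_exchange = FALSE) {
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n")[[1]]
  header <- grep("^#", text, value = TRUE)
  rxns <- list()
  for (i in seq_along(text)) {
    line <- trimws(sub("#.*$", "", text[i]))
    if (line == "") next
    parts <- strsplit(line, ";", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("line ", i, ": expected '<reaction> ; A=... n=... Ea=...'",
           call. = FALSE)
    eq <- parts[1]
    reversible <- grepl("<=>", eq, fixed = TRUE)
    arrow <- if (reversible) "<=>" else "->"
    if (!grepl(arrow, eq, fixed = TRUE))
      stop("line ", i, ": no reaction arrow ('<=>' or '->') found",
           call. = FALSE)
    sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
    if (length(sides) != 2L)
      stop("line ", i, ": malformed reaction equation", call. = FALSE)
    st <- tryCatch(
      reaction_stoichiometry(.parse_side(sides[1], i), .parse_side(sides[2], i)),
      error = function(e) stop("line ", i, ": ", conditionMessage(e),
                               call. = FALSE))
    imb <- tryCatch(.element_imbalance(st, table),
                    error = function(e) stop("line ", i, ": ",
                                             conditionMessage(e), call. = FALSE))
    if (any(abs(imb) > 1e-9))
      stop("line ", i, ": reaction is not element-balanced (",
           paste0(names(imb)[abs(imb) > 1e-9], collapse = ","), ")",
           call. = FALSE)
    getval <- function(key) {
      m <- regmatches(parts[2],
                      regexec(paste0("\\b", key, "\\s*=\\s*([-+0-9.eE]+)"),
                              parts[2]))[[1]]
      if (length(m) != 2L)
        stop("line ", i, ": missing rate parameter ", key, call. = FALSE)
      as.numeric(m[2])
    }
    rxns <- c(rxns, list(reaction(st, A = getval("A"), n = getval("n"),
                                  Ea = getval("Ea"), reversible = reversible)))
  }
  net <- reaction_network(rxns, table = table,
                          includes_graphite_exchange = includes_graphite_exchange)
  attr(net, "header") <- header
  net
}

#' Read a network file
#'
#' @param path file in the reaction-list dialect of [parse_network()]
#' @inheritParams parse_network
#' @return a `reaction_network`
#' @export
read_network <- function(path, table = thermo_table(),
                         includes_graphite_exchange = FALSE) {
  parse_network(readLines(path), table = table,
                includes_graphite_exchange = includes_graphite_exchange)
}

#' Write a network in the reaction-list dialect
#'
#' The output round-trips through [parse_network()].
#'
#' @param net a `reaction_network`
#' @param path output file, or `NULL` to return the lines
#' @param header_comment optional character vector of comment lines
#' @return the lines, invisibly if written to a file
#' @export
write_network <- function(net, path = NULL, header_comment = NULL) {
  fmt_side <- function(v) paste(ifelse(v == 1, names(v), paste(v, names(v))),
                                collapse = " + ")
  lines <- vapply(net$reactions, function(r) {
    st <- r$stoichiometry
    arrow <- if (r$reversible) "<=>" else "->"
    sprintf("%s %s %s ; A=%.6g n=%g Ea=%g", fmt_side(st$reactants), arrow,
            fmt_side(st$products), r$A, r$n, r$Ea)
  }, character(1))
  hdr <- c(if (!is.null(header_comment)) paste("#", header_comment),
           sprintf("# species: %d", length(net$species)),
           sprintf("# reactions: %d", length(net$reactions)))
  out <- c(hdr, lines)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' The packaged reduced H/C/N/O network
#'
#' A small reversible network over 21 gas-phase species with placeholder
#' modified-Arrhenius forward rates (only the equilibrium endpoint of an
#' integration is physically meaningful; absolute timescales are not).
#' Cached for the session.
#'
#' @return a `reaction_network`
#' @export
reduced_network <- function() {
  if (is.null(.ventgas_cache$network)) {
    path <- system.file("extdata", "network_reduced_hcno.txt",
                        package = "ventgas", mustWork = TRUE)
    .ventgas_cache$network <- read_network(path)
  }
  .ventgas_cache$network
}

#' Detailed-balance reverse rate constant
#'
#' `k- = k+ / Keq` with the equilibrium constant converted to the
#' concentration units implied by the reaction order:
#' `Kc = Kp * (n0)^(-dn)` where `n0` is the number density of an ideal gas
#' at the 1 bar standard state and `dn` the net mole change.
#'
#' @param rxn a [reaction()] (must be reversible)
#' @param T temperature (K)
#' @param k_forward forward rate constant at `T` (defaults to the reaction's
#'   Arrhenius value)
#' @param table thermo table
#' @return reverse rate constant in cgs concentration units
#' @export
reverse_rate_constant <- function(rxn, T, k_forward = NULL,
                                  table = thermo_table()) {
  if (!rxn$reversible)
    stop("reverse rate requested for an irreversible reaction: ",
         format(rxn$stoichiometry))
  if (is.null(k_forward)) k_forward <- .forward_rate_constant(rxn, T)
  st <- rxn$stoichiometry
  Kp <- equilibrium_constant(st, table, T)
  dn <- sum(st$products) - sum(st$reactants)
  n0 <- .number_density(1, T)           # cm^-3 at 1 bar
  Kc <- Kp * n0^dn
  k_forward / Kc
}

#' Gas-graphite exchange rates
#'
#' Returns the condensation rate constant (first order in gas-phase carbon,
#' s^-1) and the zero-order evaporation rate (cm^-3 s^-1, active while solid
#' is present) for the reaction pair C(g) <-> C(s).  Their ratio equals the
#' saturation concentration implied by the graphite vapor pressure, so the
#' exchange drives the gas-phase carbon monomer to its clamp value at steady
#' state; the absolute scale is set by `relax_rate` (the paper constrains
#' only the ratio).
#'
#' @param T temperature (K); must lie in the vapor-pressure validity window
#' @param variant vapor-pressure variant
#' @param relax_rate condensation rate constant (s^-1)
#' @param coef optional vapor-pressure coefficient override
#' @return named vector `c(condensation, evaporation)`
#' @export
graphite_exchange_rates <- function(T, variant = c("kinetics", "equilibrium"),
                                    relax_rate = 1, coef = NULL) {
  variant <- match.arg(variant)
  pvap <- graphite_vapor_pressure(T, variant, coef = coef)  # warns if outside window
  n_sat <- .number_density(pvap, T)
  c(condensation = relax_rate, evaporation = relax_rate * n_sat)
}
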