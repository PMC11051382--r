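# Shared fixtures, computed once per test run.

.cache <- new.env()

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

table1_budget <- function() {
  cached("table1_budget", mixing_ratios_to_elements(table1_gas()))
}

# Table-1 budget with carbon added far beyond saturation
supersaturated_budget <- function() {
  cached("supersat", {
    ab <- table1_budget()$abundances
    ab <- ab / sum(ab)
    ab[["C"]] <- ab[["C"]] + 1
    element_budget(ab)
  })
}

saturated_eq <- function() {
  cached("sat_eq", equilibrate_with_graphite(supersaturated_budget(),
                                             1973.15, 100,
                                             variant = "equilibrium"))
}

saturated_kin <- function() {
  cached("sat_kin", equilibrate_with_graphite(supersaturated_budget(),
                                              1973.15, 100,
                                              variant = "kinetics"))
}

ch3nc_reaction <- function() {
  reaction_stoichiometry(c(HCN = 1, CH4 = 1), c(CH3NC = 1, H2 = 1))
}
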