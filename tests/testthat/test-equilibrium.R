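tab <- thermo_table()

test_that("gas compositions map to element budgets by stoichiometry", {
  b <- table1_budget()$abundances
  # hand stoichiometry over the printed ratios (the fixture closes the
  # 0.003 rounding residual proportionally, so scale back by 0.997)
  expect_equal(unname(b[c("H", "C", "N", "O")]) * 0.9970014,
               c(0.720, 0.580, 0.114, 1.070), tolerance = 1e-5)
  pure_n2 <- gas_state(c(N2 = 1), 1500, 1)
  expect_equal(mixing_ratios_to_elements(pure_n2, tab)$abundances, c(N = 2))
  expect_error(gas_state(numeric(0), 1500, 1))
  expect_error(mixing_ratios_to_elements(
    gas_state(c(XX = 1), 1500, 1), tab), "XX")
})

test_that("the O/O2 partition matches its closed-form solution", {
  T <- 3000; P <- 1
  gas <- solve_gas_equilibrium(element_budget(c(O = 1)), T, P,
                               species = c("O", "O2"), table = tab)
  # quadratic closed form: K p_O^2 = p_O2, p_O + p_O2 = P
  K <- equilibrium_constant(reaction_stoichiometry(c(O = 2), c(O2 = 1)),
                            tab, T)
  pO <- (-1 + sqrt(1 + 4 * K * P)) / (2 * K)
  expect_equal(unname(gas$mixing_ratios["O"]), pO / P, tolerance = 1e-9)
  expect_equal(sum(gas$mixing_ratios), 1, tolerance = 1e-9)
})

test_that("single-element budgets solve as pure allotrope partitions", {
  gas <- solve_gas_equilibrium(element_budget(c(N = 1)), 1500, 1, table = tab)
  expect_gt(gas$mixing_ratios[["N2"]], 0.999999)
})

test_that("re-solving the printed gas recovers its major species", {
  gas <- solve_gas_equilibrium(table1_budget(), 1973.15, 100, table = tab)
  printed <- c(CO = 0.35, CO2 = 0.23, H2O = 0.26, H2 = 0.1, N2 = 0.057)
  for (sp in names(printed)) {
    expect_lt(abs(gas$mixing_ratios[[sp]] - printed[[sp]]) / printed[[sp]],
              0.20, label = sp)
  }
  expect_lt(max(abs(attr(gas, "residuals"))), 1e-10)
})

test_that("the solver agrees with the brute-force Gibbs oracle", {
  T <- 2200; P <- 10
  # five species, two elements: three extents span the space
  moles0 <- c(H2 = 0.45, O2 = 0.25, H2O = 0.2, OH = 0.06, H = 0.04)
  rxns <- list(reaction_stoichiometry(c(H2 = 1, O2 = 0.5), c(H2O = 1)),
               reaction_stoichiometry(c(H2 = 1), c(H = 2)),
               reaction_stoichiometry(c(H2 = 0.5, O2 = 0.5), c(OH = 1)))
  ref <- gibbs_grid_equilibrium(moles0, rxns, T, P, table = tab)
  budget <- element_budget(c(
    H = 2 * moles0[["H2"]] + 2 * moles0[["H2O"]] + moles0[["OH"]] +
      moles0[["H"]],
    O = 2 * moles0[["O2"]] + moles0[["H2O"]] + moles0[["OH"]]))
  gas <- solve_gas_equilibrium(budget, T, P, species = names(moles0),
                               table = tab)
  keep <- ref$mixing_ratios > 1e-10
  expect_lt(max(abs(gas$mixing_ratios[names(ref$mixing_ratios)][keep] -
                      ref$mixing_ratios[keep]) / ref$mixing_ratios[keep]),
            1e-6)
})

test_that("detailed balance holds at every equilibrium solution", {
  gas <- solve_gas_equilibrium(table1_budget(), 1973.15, 100, table = tab)
  p <- gas$mixing_ratios * gas$P
  rxns <- list(reaction_stoichiometry(c(CO = 1, H2O = 1), c(CO2 = 1, H2 = 1)),
               reaction_stoichiometry(c(H2 = 1, O2 = 0.5), c(H2O = 1)),
               reaction_stoichiometry(c(N2 = 1, H2 = 3), c(NH3 = 2)),
               reaction_stoichiometry(c(CH4 = 2), c(C2H2 = 1, H2 = 3)))
  for (r in rxns) {
    Q <- prod(p[names(r$products)]^r$products) /
      prod(p[names(r$reactants)]^r$reactants)
    K <- equilibrium_constant(r, tab, gas$T)
    expect_equal(Q / K, 1, tolerance = 1e-6, label = format(r))
  }
})

test_that("graphite saturation clamps the carbon activity", {
  res <- equilibrate_with_graphite(table1_budget(), 1973.15, 100,
                                   variant = "equilibrium", table = tab)
  expect_false(res$saturated)
  expect_identical(res$graphite_fraction, 0)
  # sub-saturation result equals the plain solve
  plain <- solve_gas_equilibrium(table1_budget(), 1973.15, 100, table = tab)
  expect_equal(res$gas$mixing_ratios, plain$mixing_ratios, tolerance = 1e-9)

  sat <- saturated_eq()
  expect_true(sat$saturated)
  expect_equal(sat$carbon_activity, 1, tolerance = 1e-6)
  pvap <- graphite_vapor_pressure(1973.15, "equilibrium")
  expect_equal(sat$gas$mixing_ratios[["C"]] * 100, pvap, tolerance = 1e-6)
  # composition invariant to further carbon addition
  ab <- supersaturated_budget()$abundances
  ab[["C"]] <- ab[["C"]] + 2
  more <- equilibrate_with_graphite(element_budget(ab), 1973.15, 100,
                                    variant = "equilibrium", table = tab)
  expect_equal(more$gas$mixing_ratios, sat$gas$mixing_ratios,
               tolerance = 1e-8)
  expect_gt(more$graphite_fraction, sat$graphite_fraction)
})

test_that("element conservation holds with condensed carbon counted", {
  sat <- saturated_kin()
  expect_lt(max(abs(sat$residuals), na.rm = TRUE), 1e-10)
  # carbon closure: gas carbon plus graphite equals the input inventory
  ab <- supersaturated_budget()$abundances
  x <- sat$gas$mixing_ratios
  gasC <- sum(vapply(names(x), function(s) {
    comp <- thermo_table()$species[[s]]$composition
    if ("C" %in% names(comp)) comp[["C"]] * x[[s]] else 0
  }, numeric(1)))
  gasH <- sum(vapply(names(x), function(s) {
    comp <- thermo_table()$species[[s]]$composition
    if ("H" %in% names(comp)) comp[["H"]] * x[[s]] else 0
  }, numeric(1)))
  recovered <- gasC / gasH * ab[["H"]] / (1 - sat$graphite_fraction)
  expect_equal(unname(recovered), unname(ab[["C"]]), tolerance = 1e-8)
})

test_that("saturation threshold behaves physically", {
  thr <- cached("threshold_eq",
                find_saturation_threshold(table1_budget(), 1973.15, 100,
                                          variant = "equilibrium",
                                          table = tab))
  expect_gt(thr$added_fraction, 0)
  expect_lt(thr$added_fraction, 1)
  expect_true(thr$result$saturated)
  # graphite fraction is continuous (small) just past the threshold
  expect_lt(thr$result$graphite_fraction, 0.05)
  # colder magma saturates at less added carbon
  thr_cold <- find_saturation_threshold(table1_budget(), 1673.15, 100,
                                        variant = "equilibrium", table = tab)
  expect_lt(thr_cold$added_fraction, thr$added_fraction)
  # a C/O-only budget still has a finite threshold
  thr_co <- find_saturation_threshold(element_budget(c(C = 0.3, O = 1)),
                                      1973.15, 100, variant = "equilibrium",
                                      table = tab)
  expect_true(is.finite(thr_co$added_fraction))
  # already-saturated bases are rejected informatively
  expect_error(find_saturation_threshold(supersaturated_budget(), 1973.15,
                                         100, table = tab),
               "already graphite-saturated")
})
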