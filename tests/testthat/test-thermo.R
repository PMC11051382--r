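tab <- thermo_table()

test_that("formation free energies follow the reference-element convention", {
  # reference elements vanish at 298.15 K by construction
  expect_equal(gibbs_of_formation("H2", 298.15, tab), 0, tolerance = 1e-10)
  expect_equal(gibbs_of_formation("N2", 298.15, tab), 0, tolerance = 1e-10)
  # frozen values from a standalone polynomial evaluation of the shipped CSV
  expect_equal(gibbs_of_formation("HCN", 1973.15, tab), 3.9443589834489274,
               tolerance = 1e-12)
  expect_equal(gibbs_of_formation("HCN", 298.15, tab), 47.931849529763625,
               tolerance = 1e-12)
  # evaluation at a range boundary is legal
  expect_silent(gibbs_of_formation("HCN", 200, tab))
  expect_error(gibbs_of_formation("HCN", 150, tab), "HCN")
  expect_error(gibbs_of_formation("HCN", 6500, tab), "outside")
})

test_that("the table reproduces JANAF-scale formation energies", {
  # CO at 2000 K: reference compilations give about -285.9 kJ/mol
  co <- reaction_stoichiometry(c(`C(s)` = 1, O2 = 0.5), c(CO = 1))
  expect_equal(reaction_delta_g(co, tab, 2000), -285.9, tolerance = 0.005)
  h2o <- reaction_stoichiometry(c(H2 = 1, O2 = 0.5), c(H2O = 1))
  expect_equal(reaction_delta_g(h2o, tab, 2000), -135.9, tolerance = 0.005)
})

test_that("reaction free energies are antisymmetric and satisfy Hess cycles", {
  r1 <- reaction_stoichiometry(c(H2 = 1, O2 = 0.5), c(H2O = 1))
  r1r <- reaction_stoichiometry(c(H2O = 1), c(H2 = 1, O2 = 0.5))
  T <- 1500
  expect_equal(reaction_delta_g(r1, tab, T), -reaction_delta_g(r1r, tab, T),
               tolerance = 1e-12)
  # Hess: (CO + 1/2 O2 -> CO2) + (H2 + 1/2 O2 -> H2O) equals the sum of
  # (CO + H2O -> CO2 + H2) and 2 x (H2 + 1/2 O2 -> H2O)
  a <- reaction_delta_g(reaction_stoichiometry(c(CO = 1, O2 = 0.5),
                                               c(CO2 = 1)), tab, T)
  b <- reaction_delta_g(reaction_stoichiometry(c(CO = 1, H2O = 1),
                                               c(CO2 = 1, H2 = 1)), tab, T)
  c_ <- reaction_delta_g(r1, tab, T)
  expect_equal(a, b + c_, tolerance = 1e-9)
})

test_that("stoichiometry validation rejects malformed reactions", {
  expect_error(reaction_stoichiometry(c(C2H2 = 1), c(C2H2 = 1)), "both sides")
  expect_error(reaction_stoichiometry(c(HCN = -1), c(HNC = 1)), "positive")
  unbal <- reaction_stoichiometry(c(H2 = 1), c(H2O = 1))
  expect_error(reaction_delta_g(unbal, tab, 1000), "balanced")
  expect_error(reaction_delta_g(
    reaction_stoichiometry(c(XYZ = 1), c(H2 = 1)), tab, 1000), "XYZ")
})

test_that("equilibrium constants are consistent with reaction free energies", {
  T <- 1973.15
  rxn <- reaction_stoichiometry(c(HCN = 1, CH4 = 1), c(CH3NC = 1, H2 = 1))
  K <- equilibrium_constant(rxn, tab, T)
  dg <- reaction_delta_g(rxn, tab, T)
  expect_equal(K, exp(-dg * 1e3 / (8.31446261815324 * T)), tolerance = 1e-12)
  rev <- reaction_stoichiometry(c(CH3NC = 1, H2 = 1), c(HCN = 1, CH4 = 1))
  expect_equal(K * equilibrium_constant(rev, tab, T), 1, tolerance = 1e-12)
  # scalar arithmetic on the published 114 kJ/mol value
  expect_equal(exp(-114000 / (8.3145 * 1973.15)), 9.6e-4, tolerance = 0.01)
})

test_that("the cyanoacetylene mass-action fit matches hand arithmetic", {
  expect_equal(hc3n_ln_mass_action(1000), 235.97, tolerance = 1e-4)
  expect_equal(hc3n_ln_mass_action(2000), 86.20, tolerance = 1e-4)
  grid <- seq(500, 3000, by = 25)
  expect_true(all(diff(hc3n_ln_mass_action(grid)) < 0))
  expect_error(hc3n_ln_mass_action(-5), "positive")
})

test_that("graphite vapor pressure follows its fit form and variants differ", {
  # leading terms only at 2000 K
  p <- graphite_vapor_pressure(2000, coef = c(a = 6.455, b = 2.7709e4,
                                              c = 0, d = 0))
  expect_equal(log10(p), -7.3995, tolerance = 1e-6)
  grid <- seq(1500, 4000, by = 50)
  pk <- graphite_vapor_pressure(grid, "kinetics")
  pe <- graphite_vapor_pressure(grid, "equilibrium")
  expect_true(all(diff(pk) > 0))
  expect_true(all(diff(pe) > 0))
  expect_true(all(pk != pe))
  expect_warning(graphite_vapor_pressure(800, "kinetics"), "window")
})

test_that("polynomial pieces join continuously at the range boundary", {
  for (nm in names(tab$species)) {
    lo <- gibbs_of_formation(nm, 1000 - 1e-6, tab)
    hi <- gibbs_of_formation(nm, 1000 + 1e-6, tab)
    expect_equal(lo, hi, tolerance = 1e-3, label = nm)
  }
})

test_that("table reading validates structure", {
  expect_error(thermo_species("X", c(H = 0), coeffs = data.frame()), "positive")
  bad <- data.frame(T_low = c(200, 1100), T_high = c(1000, 6000),
                    a1 = 0, a2 = 0, a3 = 0, a4 = 0, a5 = 0, a6 = 0, a7 = 0)
  expect_error(thermo_species("X", c(H = 1), phase = "gas", coeffs = bad),
               "contiguous")
  expect_error(parse_formula("H2O"), "malformed")
  expect_equal(parse_formula("C:1 H:4"), c(C = 1L, H = 4L))
})
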