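tab <- thermo_table()

test_that("a two-species isomerization relaxes with its closed-form timescale", {
  T <- 1973.15
  kf <- 0.01
  net <- parse_network(sprintf("HCN <=> HNC ; A=%g n=0 Ea=0", kf), tab)
  kr <- reverse_rate_constant(net$reactions[[1]], T, kf, tab)
  Kc <- kf / kr
  init <- gas_state(c(HCN = 1), T, 100)
  traj <- integrate_network(net, init, t_end = 200, rate_target = NA,
                            n_out = 400, table = tab)
  x <- trajectory_mixing_ratios(traj)
  # steady state [HNC]/[HCN] = Keq
  expect_equal(unname(x["HNC"] / x["HCN"]), Kc, tolerance = 1e-6)
  # relaxation e-folding time 1/(k+ + k-); tolerance e^-5 deviation is
  # reached after about five e-folds
  tau <- 1 / (kf + kr)
  ref <- c(HCN = 1 / (1 + Kc), HNC = Kc / (1 + Kc))
  tte <- time_to_equilibrium(traj, ref, tol = exp(-5))
  expect_gt(tte, 3.5 * tau)
  expect_lt(tte, 7 * tau)
})

test_that("time_to_equilibrium handles the degenerate cases", {
  T <- 1973.15
  net <- parse_network("HCN <=> HNC ; A=0 n=0 Ea=0", tab)
  init <- gas_state(c(HCN = 0.6, HNC = 0.4), T, 1)
  traj <- integrate_network(net, init, t_end = 100, rate_target = NA,
                            table = tab)
  # zero rates: trajectory constant
  expect_equal(trajectory_mixing_ratios(traj, 1),
               trajectory_mixing_ratios(traj), tolerance = 1e-12)
  # already at the queried reference: first sample qualifies
  expect_identical(time_to_equilibrium(traj, c(HCN = 0.6, HNC = 0.4),
                                       tol = 1e-6), traj$times[1])
  # never reaches a different reference: not-converged sentinel
  expect_identical(time_to_equilibrium(traj, c(HCN = 0.1, HNC = 0.9),
                                       tol = 1e-3), Inf)
})

test_that("the reduced network relaxes to the equilibrium solver's answer", {
  net <- reduced_network()
  traj <- cached("traj_reduced",
                 integrate_network(net, table1_gas(), t_end = 86400,
                                   graphite = TRUE,
                                   vapor_pressure_variant = "kinetics",
                                   table = tab))
  # element conservation along the whole trajectory (solid included)
  tot <- trajectory_element_totals(traj, tab)
  cons <- apply(tot, 2, function(v) max(abs(v - v[1])) / v[1])
  expect_lt(max(cons), 1e-8)
  expect_true(all(traj$states >= 0))
  # endpoint against the constrained equilibrium at the closed parcel's
  # final pressure
  n_end <- sum(traj$states[nrow(traj$states), traj$species])
  P_end <- n_end * 1.380649e-16 * traj$T / 1e6
  ref <- equilibrate_with_graphite(table1_budget(), traj$T, P_end,
                                   variant = "kinetics",
                                   species = net$species, table = tab)
  xk <- trajectory_mixing_ratios(traj)
  xr <- ref$gas$mixing_ratios[names(xk)]
  keep <- xr > 1e-10
  expect_lt(max(abs(xk[keep] - xr[keep]) / xr[keep]), 0.01)
})

test_that("random toy networks relax to the independent Gibbs oracle", {
  for (sd in c(1, 7, 23)) {
    ty <- toy_network(fixture_spec(seed = sd, n_species = 6), table = tab)
    traj <- integrate_network(ty$network, ty$initial, t_end = 86400,
                              table = tab)
    x <- trajectory_mixing_ratios(traj)
    rr <- ty$reference[names(x)]
    keep <- rr > 1e-10
    expect_lt(max(abs(x[keep] - rr[keep]) / rr[keep]), 0.01,
              label = paste("seed", sd))
    tot <- trajectory_element_totals(traj, tab)
    expect_lt(max(apply(tot, 2, function(v) max(abs(v - v[1])) / v[1])),
              1e-8, label = paste("seed", sd, "conservation"))
  }
})

test_that("with graphite present the carbon monomer sits at saturation", {
  T <- 1973.15
  n_tot <- 100 * 1e6 / (1.380649e-16 * T)
  mini <- parse_network("2 C <=> C2 ; A=1e-11 n=0 Ea=0", tab)
  # a slightly supersaturated carbon vapor over a solid seed: the exchange
  # must pin the monomer at the variant's saturation concentration
  for (v in c("kinetics", "equilibrium")) {
    traj <- integrate_network(mini, gas_state(c(C2 = 1e-8, N2 = 1 - 1e-8),
                                              T, 100),
                              t_end = 1e4, graphite = TRUE,
                              graphite_init = 0.1 * n_tot,
                              vapor_pressure_variant = v,
                              rate_target = NA, table = tab)
    n_sat <- graphite_vapor_pressure(T, v) * 1e6 / (1.380649e-16 * T)
    nC <- traj$states[nrow(traj$states), "C"]
    expect_equal(unname(nC / n_sat), 1, tolerance = 1e-3, label = v)
    expect_gt(traj$states[nrow(traj$states), "C(s)"], 0)
  }
  # sub-saturated gas with no solid: nothing evaporates, nothing condenses
  sub <- integrate_network(mini, gas_state(c(C2 = 1e-15, N2 = 1 - 1e-15),
                                           T, 100),
                           t_end = 100, graphite = TRUE, graphite_init = 0,
                           vapor_pressure_variant = "kinetics",
                           rate_target = NA, table = tab)
  expect_equal(unname(sub$states[nrow(sub$states), "C(s)"]), 0)
})

test_that("the kinetics/equilibrium gap is set by the vapor-pressure choice", {
  net <- reduced_network()
  T <- 1973.15
  n_tot <- 100 * 1e6 / (1.380649e-16 * T)
  sat_kin <- saturated_kin()
  x0 <- sat_kin$gas$mixing_ratios[net$species]
  g0 <- gas_state(x0 / sum(x0), T, 100)
  run <- function(variant) {
    traj <- integrate_network(net, g0, t_end = 1e6, graphite = TRUE,
                              graphite_init = 0.3 * n_tot,
                              vapor_pressure_variant = variant,
                              rate_target = 1e6, relax_rate = 1e6,
                              table = tab)
    trajectory_mixing_ratios(traj)
  }
  hcn_eq_target <- saturated_eq()$gas$mixing_ratios[["HCN"]]
  hcn_kin_target <- sat_kin$gas$mixing_ratios[["HCN"]]
  # run under the equilibrium-variant vapor pressure: the gap closes
  expect_equal(run("equilibrium")[["HCN"]], hcn_eq_target, tolerance = 0.02)
  # run under the kinetics-variant vapor pressure: the gap persists
  expect_equal(run("kinetics")[["HCN"]], hcn_kin_target, tolerance = 0.02)
  expect_gt(hcn_kin_target / hcn_eq_target, 2)
})
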