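# ventgas

Thermochemical modelling of nitrogen-rich volcanic gas interacting with
graphite-saturated crust, and the nitrile / isonitrile feedstocks it can
deliver to surface hydrothermal systems.

## The problem

High-temperature (komatiitic, ≳1500 °C) magmas degassing through crust that
carries abundant graphite produce a gas whose excess carbon condenses out as
solid graphite.  Removing that carbon from the gas phase "cleans up" the
chemistry: instead of a combinatorial mess of heavy hydrocarbons
(diacetylene and its polymers), the remaining gas is a simple mixture of CO,
CO₂, H₂, H₂O and N₂ that carries surprisingly large equilibrium abundances
of prebiotically valuable nitriles — HCN at the 0.1–1 % level and
cyanoacetylene (HC₃N) at the ppm level — plus isonitriles (HNC, and by
extension methyl isocyanide, CH₃NC).  `ventgas` implements that model for
anyone who wants to explore the parameter space: origin-of-life researchers,
volcanic-gas modellers, and anyone needing a compact H/C/N/O gas-equilibrium
solver with a condensate clamp.

## The model

* **Thermochemistry.** NASA-7 polynomials for ~34 H/C/N/O gas species plus
  graphite, generated from rigid-rotor/harmonic-oscillator statistical
  mechanics over curated spectroscopic constants, shipped as a versioned CSV
  (`inst/extdata/thermo_hcno.csv`).  Free energies, reaction ΔᵣG, and
  equilibrium constants `Keq = exp(−ΔᵣG/RT)` (1 bar standard state) derive
  from it.  Cyanoacetylene can instead be driven by a five-term mass-action
  fit `ln K(T) = 2.96×10⁵/T − 4.83 ln T − 28.47 + 1.91×10⁻³ T − 1.10×10⁻⁷ T²`
  (formation from atoms; the default for equilibrium solves).
* **Equilibrium.** An element-potential (Lagrange multiplier) solver:
  every species' partial pressure is `ln p_s = ln K_s + Σ_e ν_es λ_e`, with
  the element potentials λ and an atom-scale found by damped Newton
  iteration on logarithmic residuals, warm-started by temperature
  continuation from 6000 K.  Element conservation holds to 10⁻¹⁰ relative.
* **Graphite.** Solid carbon is handled as a saturation clamp: when the
  unconstrained carbon monomer pressure would exceed the graphite vapor
  pressure `log₁₀ p = a − b/T − c T² − d/T²`, the solve is repeated with the
  carbon activity pinned at 1 and the excess carbon booked as condensed
  graphite.  Two coefficient sets ship (a "kinetics" and an "equilibrium"
  variant, differing by a factor ~4 in saturation pressure at 1973 K); their
  difference is exactly what separates the two branches of the published
  graphite-addition sweeps.
* **Kinetics.** A reversible reaction-network integrator
  (`d[X]/dt = P_X − L_X[X]`, stiff `deSolve::lsoda`) whose reverse rate
  constants are set from the equilibrium constants (`k₋ = k₊/Keq`, detailed
  balance), plus a zero-dimensional gas↔graphite exchange whose
  evaporation/condensation ratio equals the saturation concentration.
  Integrations therefore relax to the same equilibria the solver computes —
  a property the test suite verifies against an independent brute-force
  Gibbs-minimization oracle.
* **Scenarios.** Graphite-addition sweeps, temperature sweeps at
  saturation, H/C/N/O–T–P sensitivity grids, an oxygen-fugacity diagnostic
  relative to the QFM buffer, and the CH₃NC estimator
  `[CH₃NC] = exp(−ΔᵣG/RT)[HCN][CH₄]/[H₂]`.

## Worked example

```r
library(ventgas)

# element budget of the fiducial 1700 degC, 100 bar magmatic gas
budget <- mixing_ratios_to_elements(table1_gas())

# add carbon far beyond saturation and equilibrate with graphite
ab <- budget$abundances / sum(budget$abundances)
ab[["C"]] <- ab[["C"]] + 1
sat <- equilibrate_with_graphite(element_budget(ab), 1973.15, 100,
                                 variant = "equilibrium")
sat
#> <equilibrium_result> saturated=TRUE graphite_fraction=0.6500 carbon_activity=1
#> <gas_state> T = 1973.15 K, P = 100 bar, 34 species
#>   CO      7.1917e-01
#>   H2      2.3471e-01
#>   N2      3.7564e-02
#>   CH4     2.7006e-03
#>   H2O     2.1527e-03
#>   HCN     1.8859e-03
#>   CO2     1.3878e-03
#>   C2H2    1.6972e-04
```

At saturation 65 % of the carbon inventory sits in graphite; the gas carries
HCN at 1.9×10⁻³ (0.19 %), HNC at 8.3×10⁻⁵ and — with the mass-action fit —
HC₃N at 1.0×10⁻⁷, while diacetylene is scrubbed to 2×10⁻⁸.  The saturation
threshold itself:

```r
thr <- find_saturation_threshold(budget, 1973.15, 100, variant = "equilibrium")
thr$added_over_initial_carbon
#> [1] 0.8525401
```

i.e. the gas stops changing once the added carbon reaches ~0.85× the
initial carbon inventory (≈0.8, the saturation limit of the fiducial
system).  The methyl isocyanide estimate at the saturated composition:

```r
x <- sat$gas$mixing_ratios
ch3nc_estimate(1973.15, hcn = x[["HCN"]], ch4 = x[["CH4"]], h2 = x[["H2"]])
#> [1] 2.22117e-08
```

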