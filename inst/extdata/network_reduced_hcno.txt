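# reduced_hcno v1.0 -- reduced reversible H/C/N/O network
# Placeholder modified-Arrhenius forward rates (k = A T^n exp(-Ea/T), Ea in K,
# cgs units by reaction order), chosen so a 100-bar magmatic gas equilibrates
# within ~1e3-1e4 s; only the equilibrium endpoint is physically asserted.
# Reverse rates are derived from equilibrium constants at run time.
# species: 21
# reactions: 21
2 H <=> H2 ; A=1e-11 n=0 Ea=0
2 O <=> O2 ; A=1e-11 n=0 Ea=0
2 N <=> N2 ; A=1e-11 n=0 Ea=0
H2 + O <=> OH + H ; A=1e-11 n=0 Ea=0
OH + H2 <=> H2O + H ; A=1e-11 n=0 Ea=0
O2 + H <=> OH + O ; A=1e-11 n=0 Ea=0
CO + OH <=> CO2 + H ; A=1e-11 n=0 Ea=0
C + O2 <=> CO + O ; A=1e-11 n=0 Ea=0
CH4 + H <=> CH3 + H2 ; A=1e-11 n=0 Ea=0
C2H2 <=> 2 C + H2 ; A=1e-2 n=0 Ea=0
C4H2 + H2 <=> 2 C2H2 ; A=1e-11 n=0 Ea=0
C2H2 + 3 H2 <=> 2 CH4 ; A=1e-62 n=0 Ea=0
N2 + 3 H2 <=> 2 NH3 ; A=1e-62 n=0 Ea=0
C + N <=> CN ; A=1e-11 n=0 Ea=0
CN + H2 <=> HCN + H ; A=1e-11 n=0 Ea=0
HCN <=> HNC ; A=1e-2 n=0 Ea=0
CO + H <=> HCO ; A=1e-11 n=0 Ea=0
CO + H2 <=> H2CO ; A=1e-11 n=0 Ea=0
2 CO <=> CO2 + C ; A=1e-11 n=0 Ea=0
C2H2 + N2 <=> 2 HCN ; A=1e-11 n=0 Ea=0
CO + 3 H2 <=> CH4 + H2O ; A=1e-62 n=0 Ea=0
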