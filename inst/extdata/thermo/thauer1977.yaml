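# Standard Gibbs free energies of formation (kJ/mol, 298.15 K) for the
# species used in anaerobic lactate / nitrogen-oxide catabolism, from the
# classical anaerobic-microbiology compilation (Thauer, Jungermann & Decker
# 1977). H+ carries 0 here; the biochemical-standard pH correction
# (-RT ln10 * pH per proton) is applied at evaluation time.
provenance: "Thauer/Jungermann/Decker 1977 compilation, gaseous CO2 and N oxides, pH correction applied to H+ only"
temperature: 298.15
pH: 7
species:
  - { name: lactate,  formula: C3H5O3, charge: -1, dGf_prime: -517.81 }
  - { name: pyruvate, formula: C3H3O3, charge: -1, dGf_prime: -474.63 }
  - { name: acetate,  formula: C2H3O2, charge: -1, dGf_prime: -369.41 }
  - { name: formate,  formula: CHO2,   charge: -1, dGf_prime: -351.04 }
  - { name: CO2,      formula: CO2,    charge: 0,  dGf_prime: -394.36, phase: g }
  - { name: HCO3-,    formula: CHO3,   charge: -1, dGf_prime: -586.85 }
  - { name: nitrate,  formula: NO3,    charge: -1, dGf_prime: -111.34 }
  - { name: nitrite,  formula: NO2,    charge: -1, dGf_prime: -37.20 }
  - { name: "NO",     formula: "NO",     charge: 0,  dGf_prime: 86.57,  phase: g }
  - { name: N2O,      formula: N2O,    charge: 0,  dGf_prime: 104.18, phase: g }
  - { name: N2,       formula: N2,     charge: 0,  dGf_prime: 0.0,    phase: g }
  - { name: ammonium, formula: NH4,    charge: 1,  dGf_prime: -79.37 }
  - { name: H2O,      formula: H2O,    charge: 0,  dGf_prime: -237.17 }
  - { name: H2,       formula: H2,     charge: 0,  dGf_prime: 0.0,    phase: g }
  - { name: "H+",     formula: H,      charge: 1,  dGf_prime: 0.0 }
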