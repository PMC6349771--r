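# I. calvum truncated denitrification chain (nitrite -> N2O via NirK/qNor).
# Per-nitrite ledger: 1 MKH2 through NADH dehydrogenase (+4) and the bc1
# complex (+4) = gross 8; NirK consumes 2 H+ in the periplasm reducing
# nitrite to NO; qNor is net zero (consumes 2 H+ making N2O, releases 2 H+
# at its quinol site) and regenerates no MKH2. Net: 6 H+ per nitrite.
# NarG is listed for the shared nitrate step but excluded from per-nitrite
# ledgers by default.
pathway: denitrification
electrons_per_nitrite: 2
modules:
  - name: NADH dehydrogenase
    scope: quinol_generation
    h_translocated_per_quinol: 4
  - name: bc1 complex
    scope: nitrite_to_no
    h_translocated_per_quinol: 4
  - name: NirK
    scope: nitrite_to_no
    h_consumed_periplasm_per_reaction: 2
  - name: qNor
    scope: no_to_n2o
    h_released_periplasm_per_quinol: 2
    h_consumed_periplasm_per_reaction: 2
  - name: NarG
    scope: nitrate
    h_consumed_periplasm_per_reaction: -2
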