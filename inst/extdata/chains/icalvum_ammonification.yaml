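# I. calvum respiratory ammonification chain (nitrite -> ammonium via
# NrfAH). Six electrons per nitrite = 3 MKH2. NADH dehydrogenase
# translocates 4 H+ per MKH2 (+12); formate dehydrogenase contributes a
# flat +2 per nitrite turnover (negative "consumption" = credit); NrfH
# liberates 2 H+ per MKH2 oxidized at its quinol site (+6); NrfA consumes
# 8 H+ in the periplasm reducing nitrite to ammonium. Net: 12 H+ per
# nitrite.
pathway: ammonification
electrons_per_nitrite: 6
modules:
  - name: NADH dehydrogenase
    scope: quinol_generation
    h_translocated_per_quinol: 4
  - name: formate dehydrogenase
    scope: quinol_generation
    h_consumed_periplasm_per_reaction: -2
  - name: NrfH
    scope: nitrite_to_nh4
    h_released_periplasm_per_quinol: 2
  - name: NrfA
    scope: nitrite_to_nh4
    h_consumed_periplasm_per_reaction: 8
  - name: NarG
    scope: nitrate
    h_consumed_periplasm_per_reaction: -2
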