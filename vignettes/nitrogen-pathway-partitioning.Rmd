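---
title: "Partitioning dissimilated nitrogen between ammonification and denitrification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning dissimilated nitrogen between ammonification and denitrification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrofate)
```

## The scientific problem

Some bacteria carry both dissimilatory nitrite-reduction pathways in one
genome: respiratory ammonification (DNRA, nitrite reduced to ammonium by the
pentaheme cytochrome c nitrite reductase NrfA) and denitrification (nitrite
reduced via NO to N~2~O by NirK and qNor). How such a dual-pathway organism
splits nitrite between the two routes decides whether fixed nitrogen stays
in the system (ammonium) or leaves it as gas (N~2~O), so the partitioning
rule matters for both ecosystem budgets and greenhouse-gas accounting.

The classical predictor of pathway selection is the C:NO~3~^−^ ratio of the
medium. `nitrofate` implements the quantitative toolkit needed to probe a
competing hypothesis — that absolute resource *concentration*, not the
ratio, tips the balance — in four independent currencies:

1. **Protein elemental cost (ARSC).** Mean side-chain carbon and nitrogen
   atoms per residue, comparing enzyme families with Welch and permutation
   tests.
2. **Redox thermodynamics.** Exactly balanced donor/acceptor couples and
   biochemical-standard Gibbs energies, per reaction, per nitrite and per
   electron.
3. **Proton bookkeeping.** A configurable ledger of periplasmic proton
   credits and debits per nitrite reduced for branched, menaquinone-based
   electron transport chains.
4. **Mass balance and growth.** Net metabolite changes, pathway fractions,
   nitrogen recovery, growth rates from OD curves, and the growth-rate
   versus ammonification-fraction regression.

A fifth module generates fully ground-truthed synthetic data so the whole
pipeline is testable without wet-lab measurements.

## ARSC: atoms per residue side-chain

Every peptide-bonded residue shares a backbone of 2 C, 1 N and 2 O, so
elemental frugality shows up in the side chains. For a protein with
residues $r_1,\dots,r_L$,

$$\mathrm{ARSC}_E = \frac{1}{L}\sum_{i=1}^{L} E(r_i),$$

where $E(r)$ is the side-chain count of element $E \in \{C, N\}$. The
counts derive from the free-amino-acid molecular formulas by subtracting
the backbone constants; the package asserts that derivation for all 20
residues. ARSC is computed per protein and then averaged per family (not
pooled over concatenated residues), so each sequence contributes equally
regardless of length.

Design choices where the procedure was open:

* **Ambiguity codes.** X/B/Z/J/U/O, stops and gaps are dropped from both
  numerator and denominator by default (the length normalisation then
  still refers to the residues actually counted); a `strict` policy errors
  instead. No published convention exists for this corner.
* **Inference.** "t-test" admits many variants, so the package reports
  both a Welch two-sample test and a label-permutation test on the mean
  difference (10,000 permutations by default, seed mandatory). For 10 or
  fewer sequences the permutation test enumerates all label splits and is
  exact.

The planted-difference generator (`generate_protein_set()`) draws residues
i.i.d. from an exponentially tilted composition whose expected ARSC is
shifted by a requested delta; the tilt is found by convex optimisation of
the exponential-family dual, and the achieved expectation is recorded.
Because real nitrite-reductase sequences are not bundled, green ARSC tests
establish that the statistic and its inference behave correctly — not that
any particular enzyme family is cost-minimised.

## Redox couples and Gibbs free energies

Half reactions are stored in the reduction direction and completed
automatically with H~2~O and H^+^; the electron count is the charge
difference of the completed sides. Coupling a donor oxidation with an
acceptor reduction scales both to the least common multiple of their
electron counts, cancels electrons and reduces to smallest integers.
Element and charge conservation are asserted exactly (integer arithmetic);
an imbalance is an internal error, never a silent result.

With a formation-energy table $\Delta G^\circ_f$,

$$\Delta G^{\circ\prime} = \sum_s \nu_s\, \Delta G^{\circ}_f(s)
  \; - \; \nu_{H^+} RT \ln(10)\,\mathrm{pH},$$

the proton term converting to the biochemical standard state (pH 7,
298.15 K by default). The bundled table is transcribed from the classical
anaerobic-microbiology compilation (Thauer, Jungermann & Decker 1977),
with CO~2~ and the nitrogen oxides as gaseous species; this choice
reproduces the literature values for the lactate/nitrite couples
(−787 vs −781 kJ for nitrite → ammonium, −1273 vs −1248 kJ for
nitrite → N~2~O, i.e. 0.8% and 2.0% off) within the 5% one must grant for
table provenance. Every Gibbs-energy result carries the table's
provenance string.

Two numerical notes. First, the balanced ammonification couple is

$$\mathrm{lactate}^- + 2\,\mathrm{NO_2^-} + 5\,\mathrm{H^+}
  \rightarrow 3\,\mathrm{CO_2} + 2\,\mathrm{NH_4^+} + \mathrm{H_2O},$$

with 5 protons — the only proton count that balances charge. Second, the
published per-nitrite energies (−399 and −217 kJ) are not exactly the
published totals divided by the nitrite stoichiometry (−781/2 = −390.5,
−1248/6 = −208); the package computes per-basis values by plain division
and does not force agreement with either reading — both land within 5%.

Concentration corrections (reaction quotients) are deliberately out of
scope: only standard-state $\Delta G^{\circ\prime}$ is computed.

## The proton ledger

Each menaquinol (MKH~2~) carries two electrons, so a pathway consuming
$E$ electrons per nitrite turns over $E/2$ quinols per nitrite. Modules
credit protons translocated per quinol (pumps and Q-loops), credit protons
released on the periplasmic side per quinol oxidised at their site, and
debit protons consumed in the periplasm per catalytic turnover. A negative
per-reaction consumption expresses a flat per-turnover credit; that is how
the formate-dehydrogenase contribution ("+2 H^+^ per nitrite") is encoded,
the only reading that reproduces the published net of 12.

The bundled reference chains give, per nitrite:

| pathway | MKH~2~ | gross H^+^ | net H^+^ |
|---|---|---|---|
| denitrification (NirK/qNor) | 1 | 8 | 6 |
| ammonification (NrfAH + FDH) | 3 | 12 | 12 |

Two conventions deserve emphasis. The ledger follows the published
arithmetic in crediting both the NADH dehydrogenase and the bc~1~ complex
with the full quinol flux per nitrite, although strictly one of the two
electrons reaches N~2~O via qNor without passing bc~1~; the ledger is a
bookkeeping device, not a flux model. And the shared nitrate-reduction
step is excluded from per-nitrite ledgers by default; the
membrane-bound-versus-periplasmic nitrate reductase alternatives (NarG
+2 vs NapA −2, a swing of 4 H^+^ per nitrate) are scored with
`module_swap_delta()`.

## Mass balance, fractions and growth

All amounts convert to µmol via the vessel volume (mM × mL). N~2~O is
always put on the nitrogen basis (×2). The ammonification fraction is

$$f_\mathrm{amm} = \frac{\max(\Delta \mathrm{NH_4^+}, 0)}
 {\max(\Delta \mathrm{NH_4^+}, 0) + \Delta \mathrm{N_2O\!-\!N}},$$

with a net-negative ammonium change (assimilation exceeding production)
contributing zero, flagged and warned — the signed net change remains
available, but fractions stay in [0, 1]. Nitrogen recovery is
100 × products-N / dissimilated-N; the published 97.4% figure is validated
as a formula (13 + 24 = 37 µmol over an inferred 38 µmol denominator),
since the denominator is not printed.

Growth rates come from a log-linear least-squares fit on an exponential
window. The default strategy scans all windows with ≥ 4 points, ≥ 3 h span
*and at least a 1.5-fold signal increase*, keeping the window with maximal
r² (≥ 0.98 required). The fold-increase requirement is an addition born of
testing: without it, 4-point windows of stationary-phase observation noise
occasionally pass the r² gate and return spurious near-zero growth rates.
The fitted window is always reported. Note that a specific growth rate of
0.4 h^−1^ corresponds to 0.58 doublings per hour (µ/ln 2); the package
reports both and leaves any internally inconsistent published phrasing
alone.

## What the simulator emulates — and what it does not

`simulate_batch_culture()` integrates a two-phase model with fixed-step
RK4:

* **Phase 1 (growth).** Dual-Monod growth on lactate and nitrate
  ($\mu = \mu_{max} \frac{L}{K_L+L}\frac{N}{K_N+N}$), nitrate reduced
  stoichiometrically to nitrite, biomass rising with a fixed OD yield.
* **Phase 2 (stationary).** Once nitrate (or lactate) is exhausted, growth
  stops and nitrite bleeds off at a slow first-order rate, split
  $f_\mathrm{amm}^{true}$ to ammonium (minus a small assimilated share)
  and $(1-f_\mathrm{amm}^{true})/2$ to N~2~O molecules.

The two phases are blended by a steep smooth weight in the limiting
substrate (quartic sigmoid at the exhaustion threshold) rather than a hard
switch, keeping the right-hand side continuous so the integrator retains
4th-order convergence; halving the default step (0.02 h) changes sampled
tracks by < 0.01%. Nitrogen and carbon balances are asserted at every
step. Observation noise is multiplicative, seeded, applied only to emitted
tracks and clipped at zero; the clean tracks and all ground truth ride
along in the output.

Default parameter choices (made once, as the package's stated world):
µ~max~ 0.25 h^−1^ and K~s~ of 0.02 mM (lactate) / 0.1 mM (nitrate) —
high-affinity uptake typical of organisms facing sub-mM substrate; OD
yield 0.05 per mM lactate; 4 NO~3~^−^ reduced per lactate consumed (two
thirds of lactate electrons catabolic, one third of carbon to biomass);
stationary nitrite turnover 10^−3^ h^−1^, slow enough that nitrite
persists for hundreds of hours as observed in extended incubations; 3% of
pathway-produced ammonium re-assimilated, consistent with ~97% nitrogen
recovery; OD sampled hourly (automated readers), metabolites alongside.

`generate_endpoint_panel()` reproduces the two-concentration design:
ratios {4, 2, 1, 0.5, 0.1} × nitrate {12, 1.2} mM, lactate set from the
ratio. The true ammonification fraction follows a declared decreasing
logistic in lactate concentration (`coupling_low_carbon()`), and each
culture's µ~max~ is scaled by $1 + 1.5\,f_\mathrm{amm}^{true}$ — the
growth advantage of ammonifying cultures that is the central physiological
observation being emulated. The coupling strength matters: with a much
weaker value the Monod concentration confounder (less substrate → slower
growth) dominates and the panel regression flips sign, contradicting the
declared positive coupling; 1.5 makes the advantage roughly the 2–3-fold
spread seen across real treatments.

Known limitations: no mechanistic electron-transport or redox-poise model
(phase switching is phenomenological); no nitrite/NO toxicity; no
low-resource ammonium oscillations; incomplete-oxidation byproducts
(acetate/formate leaks) are off by default; process stochasticity is not
modelled (noise is observation-only). A green pipeline-recovery test
therefore establishes the estimators' correctness on this stated world,
not the biology of any particular organism.

## Worked example

```{r example}
sim <- simulate_batch_culture(sim_params(f_amm_true = 0.7,
                                         noise_sigma = 0.02, seed = 42))
an <- analyze_culture(sim$series)
an$partition
an$growth

led <- tally_ledger(icalvum_chain("ammonification"))
led

tabl <- default_thermo_table()
rxn <- couple_half_reactions(std_half_reaction("lactate/CO2", tabl),
                             std_half_reaction("nitrite/ammonium", tabl),
                             tabl)
gibbs_free_energy(rxn, tabl)
```

## Numerical and degenerate-input policy

* Reaction coefficients are exact small integers; conservation checks use
  integer arithmetic with a 10^−9^ guard for the merged vectors.
* A half reaction coupled with its own reverse cancels to the null
  reaction (all coefficients zero, $\Delta G = 0$); normalising the null
  reaction errors.
* Permutation p-values from sampling use the add-one estimator
  $(h+1)/(B+1)$ and can never be 0; enumeration returns the exact tail
  fraction.
* Growth fits refuse curves with no qualifying window ("no exponential
  phase detected") rather than returning a meaningless slope.
* The simulator dumps its full parameter set on any non-finite state.
* All randomness flows from explicit integer seeds; derived per-culture
  seeds stay below 2^31.
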