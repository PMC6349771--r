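tab <- default_thermo_table()

test_that("half reactions auto-complete H2O/H+ and derive electron counts", {
  lac <- std_half_reaction("lactate/CO2", tab)
  expect_equal(lac$n_electrons, 12L)
  expect_equal(unname(lac$oxidized_side["H+"]), 11)
  expect_equal(unname(lac$reduced_side["H2O"]), 3)
  amm <- std_half_reaction("nitrite/ammonium", tab)
  expect_equal(amm$n_electrons, 6L)
  expect_equal(unname(amm$oxidized_side["H+"]), 8)  # 6 e- and 8 H+ per nitrite
  n2o <- std_half_reaction("nitrite/N2O", tab)
  expect_equal(n2o$n_electrons, 4L)
  expect_error(half_reaction(c(nitrite = 1), c(nitrite = 1), table = tab),
               "non-positive electron count")
  expect_error(half_reaction(c(nitrite = 1), c(ammonium = 1),
                             n_electrons = 4, table = tab), "expected 4")
})

test_that("coupling scales by electron LCM: lactate 1 : nitrite 2 and 1 : 6", {
  lac <- std_half_reaction("lactate/CO2", tab)
  amm <- couple_half_reactions(lac, std_half_reaction("nitrite/ammonium", tab), tab)
  expect_equal(unname(amm$coefficients["lactate"]), -1)
  expect_equal(unname(amm$coefficients["nitrite"]), -2)  # LCM(12,6)/6 = 2
  expect_equal(unname(amm$coefficients["ammonium"]), 2)
  expect_equal(amm$n_electrons_transferred, 12)
  den <- couple_half_reactions(lac, std_half_reaction("nitrite/N2O", tab), tab)
  expect_equal(unname(den$coefficients["lactate"]), -1)
  expect_equal(unname(den$coefficients["nitrite"]), -6)  # LCM(12,4)/4 * 2 = 6
  expect_equal(unname(den$coefficients["N2O"]), 3)
})

test_that("a half reaction coupled with its own reverse cancels to nothing", {
  hr <- std_half_reaction("nitrite/ammonium", tab)
  null_rxn <- couple_half_reactions(hr, hr, tab)
  expect_length(null_rxn$coefficients, 0)
  expect_equal(as.numeric(gibbs_free_energy(null_rxn, tab)), 0)
  expect_error(normalize_energy(null_rxn, 0, "per_nitrite", tab),
               "zero coefficient")
})

test_that("every coupled reaction conserves elements and charge exactly", {
  donors <- c("lactate/CO2", "formate/CO2", "acetate/CO2")
  acceptors <- c("nitrate/nitrite", "nitrite/ammonium", "nitrite/NO",
                 "NO/N2O", "nitrite/N2O", "N2O/N2")
  for (d in donors) for (a in acceptors) {
    rxn <- couple_half_reactions(std_half_reaction(d, tab),
                                 std_half_reaction(a, tab), tab)
    totals <- reaction_element_totals(as.list(rxn$coefficients),
                                      SPECIES_FORMULAS, SPECIES_CHARGES)
    for (v in totals) expect_equal(unname(v), 0)
  }
})

test_that("Delta G reproduces the published lactate/nitrite couples within 5%", {
  lac <- std_half_reaction("lactate/CO2", tab)
  amm <- couple_half_reactions(lac, std_half_reaction("nitrite/ammonium", tab), tab)
  den <- couple_half_reactions(lac, std_half_reaction("nitrite/N2O", tab), tab)
  dg_amm <- as.numeric(gibbs_free_energy(amm, tab))
  dg_den <- as.numeric(gibbs_free_energy(den, tab))
  expect_lt(abs(dg_amm - (-781)) / 781, 0.05)
  expect_lt(abs(dg_den - (-1248)) / 1248, 0.05)
  # itemized terms sum to the total and carry provenance
  dg_full <- gibbs_free_energy(amm, tab)
  expect_equal(sum(attr(dg_full, "terms")$term), as.numeric(dg_full))
  expect_match(attr(dg_full, "provenance"), "Thauer")
  expect_error(gibbs_free_energy(structure(list(
    coefficients = c(unobtainium = 1), n_electrons_transferred = 1,
    reference = list(donor = "unobtainium")), class = "balanced_reaction"), tab),
    "unobtainium")
})

test_that("normalization divides by the basis coefficient", {
  lac <- std_half_reaction("lactate/CO2", tab)
  den <- couple_half_reactions(lac, std_half_reaction("nitrite/N2O", tab), tab)
  expect_equal(normalize_energy(den, -1248, "per_nitrite"), -1248 / 6)
  expect_equal(normalize_energy(den, -1248, "per_electron"), -1248 / 12)
  expect_equal(normalize_energy(den, -1248, "per_donor"), -1248)
  # per-basis value times coefficient returns the total exactly
  dg <- as.numeric(gibbs_free_energy(den, tab))
  expect_equal(normalize_energy(den, dg, "per_nitrite") *
                 abs(unname(den$coefficients["nitrite"])), dg)
})

test_that("Delta G is antisymmetric and additive over reaction combination", {
  lac <- std_half_reaction("lactate/CO2", tab)
  A <- couple_half_reactions(lac, std_half_reaction("nitrate/nitrite", tab), tab)
  B <- couple_half_reactions(lac, std_half_reaction("nitrite/ammonium", tab), tab)
  C <- couple_half_reactions(lac, half_reaction(c(nitrate = 1), c(ammonium = 1),
                                                table = tab), tab)
  dgA <- as.numeric(gibbs_free_energy(A, tab))
  dgB <- as.numeric(gibbs_free_energy(B, tab))
  dgC <- as.numeric(gibbs_free_energy(C, tab))
  # reverse reaction: negate all coefficients
  revB <- B; revB$coefficients <- -B$coefficients
  expect_equal(as.numeric(gibbs_free_energy(revB, tab)), -dgB)
  # C (2 lactate + 3 nitrate -> 3 ammonium, 24 e-) = 1/2 A + 3/2 B
  scale_C <- abs(unname(C$coefficients["lactate"])) / 2
  expect_equal(dgC / scale_C, 0.5 * dgA + 1.5 * dgB, tolerance = 1e-10)
})

test_that("pathway energetics ordering: per electron vs per nitrite", {
  lac <- std_half_reaction("lactate/CO2", tab)
  amm <- couple_half_reactions(lac, std_half_reaction("nitrite/ammonium", tab), tab)
  den <- couple_half_reactions(lac, std_half_reaction("nitrite/N2O", tab), tab)
  dg_amm <- as.numeric(gibbs_free_energy(amm, tab))
  dg_den <- as.numeric(gibbs_free_energy(den, tab))
  # denitrification releases more energy per electron ...
  expect_lt(normalize_energy(den, dg_den, "per_electron"),
            normalize_energy(amm, dg_amm, "per_electron"))
  # ... but ammonification releases more per nitrite
  expect_lt(normalize_energy(amm, dg_amm, "per_nitrite"),
            normalize_energy(den, dg_den, "per_nitrite"))
})

test_that("the bundled thermo table file round-trips to the built-in table", {
  path <- system.file("extdata", "thermo", "thauer1977.yaml",
                      package = "nitrofate")
  loaded <- read_thermo_table(path)
  expect_equal(loaded$pH, 7)
  for (nm in names(tab$species))
    expect_equal(loaded$species[[nm]]$dGf_prime, tab$species[[nm]]$dGf_prime)
})

test_that("C:NO3- ratio follows the media-recipe formula", {
  expect_equal(c_to_no3_ratio(media_recipe(donor_mM = 8, acceptor_mM = 12)), 2)
  expect_equal(c_to_no3_ratio(media_recipe(donor_mM = 1.6, acceptor_mM = 1.2)), 4)
  expect_equal(c_to_no3_ratio(media_recipe(donor_mM = 0, acceptor_mM = 12)), 0)
  expect_error(c_to_no3_ratio(media_recipe(donor_mM = 8, acceptor_mM = 0)),
               "must be > 0")
  # methanol-style 1-C donor against a 1-N acceptor: plain concentration ratio
  expect_equal(c_to_no3_ratio(media_recipe(donor = "formate", donor_nC = 1,
                                           donor_mM = 10, acceptor_mM = 5)), 2)
})
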