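# Shared fixture builders; everything is generated in code.

profiles_of <- function(...) {
  seqs <- c(...)
  compute_arsc_set(lapply(seq_along(seqs), function(i)
    protein_record(paste0("p", i), seqs[i])))
}

# Independent residue chemistry: side-chain C/N for all 20 standard amino
# acids, written down from their textbook molecular formulas (free amino
# acid minus the 2-C/1-N backbone). Used as the oracle for the embedded
# table.
EXPECTED_SIDECHAIN <- data.frame(
  code = c("A","R","N","D","C","E","Q","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V"),
  C = c(1, 4, 2, 2, 1, 3, 3, 0, 4, 4, 4, 4, 3, 7, 3, 1, 2, 9, 7, 3),
  N = c(0, 3, 1, 0, 0, 0, 1, 0, 2, 0, 0, 1, 0, 0, 0, 0, 0, 1, 0, 0),
  stringsAsFactors = FALSE
)

# Element totals of a balanced reaction recomputed from scratch (formula
# strings parsed here, not via package internals).
reaction_element_totals <- function(coeffs, formula_strings, charges) {
  parse <- function(s) {
    parts <- regmatches(s, gregexpr("[A-Z][a-z]?[0-9]*", s))[[1]]
    el <- sub("[0-9]*$", "", parts)
    n <- as.integer(ifelse(grepl("[0-9]+$", parts),
                           sub("^[A-Za-z]+", "", parts), "1"))
    tapply(n, el, sum)
  }
  totals <- list(charge = 0)
  for (nm in names(coeffs)) {
    f <- parse(formula_strings[[nm]])
    for (el in names(f))
      totals[[el]] <- (if (is.null(totals[[el]])) 0 else totals[[el]]) +
        coeffs[[nm]] * f[[el]]
    totals$charge <- totals$charge + coeffs[[nm]] * charges[[nm]]
  }
  totals
}

SPECIES_FORMULAS <- c(lactate = "C3H5O3", CO2 = "CO2", nitrate = "NO3",
                      nitrite = "NO2", NO = "NO", N2O = "N2O", N2 = "N2",
                      ammonium = "NH4", H2O = "H2O", "H+" = "H",
                      formate = "CHO2", acetate = "C2H3O2")
SPECIES_CHARGES <- c(lactate = -1, CO2 = 0, nitrate = -1, nitrite = -1,
                     NO = 0, N2O = 0, N2 = 0, ammonium = 1, H2O = 0,
                     "H+" = 1, formate = -1, acetate = -1)
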