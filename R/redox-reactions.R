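# Exact balancing of donor/acceptor redox couples and Delta-G evaluation.
#
# Half reactions are stored in the reduction direction (oxidized side +
# n e- -> reduced side). The constructor completes the oxygen and hydrogen
# balance with implied H2O and H+, then verifies element-by-element and
# charge balance exactly in integer arithmetic. Coupling two half reactions
# scales them to the least common multiple of their electron counts so that
# electrons cancel, and reduces the merged coefficients to smallest
# integers.

# Safe lookup in a named numeric vector: absent name -> 0.
num_get <- function(v, nm) {
  x <- unname(v[nm])
  if (length(x) == 0L || is.na(x)) 0 else x
}

side_elements <- function(side, formulas) {
  out <- numeric(0)
  for (nm in names(side)) {
    f <- formulas[[nm]]$formula
    for (el in names(f)) out[el] <- num_get(out, el) + side[[nm]] * f[[el]]
  }
  out
}

side_charge <- function(side, formulas) {
  sum(vapply(names(side), function(nm) side[[nm]] * formulas[[nm]]$charge, 0))
}

#' Construct a balanced half reaction
#'
#' Give the redox-active species only; H2O and H+ are supplied automatically
#' to complete the O and H balance. The electron count is derived from the
#' charge difference of the two completed sides and, when `n_electrons` is
#' supplied, verified against it.
#'
#' @param oxidized Named numeric vector of species coefficients on the
#'   oxidized (electron-accepting) side, e.g. `c(nitrite = 1)`.
#' @param reduced Named numeric vector for the reduced side,
#'   e.g. `c(ammonium = 1)`.
#' @param n_electrons Optional expected electron count (positive integer).
#' @param table A [thermo_table()] supplying formulas and charges.
#' @return A `half_reaction` object.
#' @export
#' @examples
#' half_reaction(c(nitrite = 1), c(ammonium = 1))  # 6-electron reduction
half_reaction <- function(oxidized, reduced, n_electrons = NULL,
                          table = default_thermo_table()) {
  ox <- as.list(oxidized); red <- as.list(reduced)
  all_named <- c(names(ox), names(red), "H2O", "H+")
  formulas <- lapply(stats::setNames(all_named, all_named),
                     function(nm) lookup_species(table, nm))

  bal <- function(side, nm, amount) {
    if (amount == 0) return(side)
    side[[nm]] <- (side[[nm]] %||% 0) + amount
    side
  }
  # oxygen balance with water
  dO <- num_get(side_elements(ox, formulas), "O") -
        num_get(side_elements(red, formulas), "O")
  if (dO > 0) red <- bal(red, "H2O", dO) else ox <- bal(ox, "H2O", -dO)
  # hydrogen balance with protons
  dH <- num_get(side_elements(ox, formulas), "H") -
        num_get(side_elements(red, formulas), "H")
  if (dH > 0) red <- bal(red, "H+", dH) else ox <- bal(ox, "H+", -dH)

  el_ox <- side_elements(ox, formulas); el_red <- side_elements(red, formulas)
  els <- union(names(el_ox), names(el_red))
  for (el in els) {
    if (!isTRUE(all.equal(el_ox[el] %||% 0, el_red[el] %||% 0)))
      stopf("half reaction does not balance in element %s", el)
  }
  ne <- side_charge(ox, formulas) - side_charge(red, formulas)
  if (ne <= 0) stopf("half reaction has non-positive electron count (%s)", ne)
  if (!is.null(n_electrons) && ne != n_electrons)
    stopf("half reaction transfers %d electrons, expected %d", ne, n_electrons)

  structure(list(oxidized_side = unlist(ox), reduced_side = unlist(red),
                 n_electrons = as.integer(ne)),
            class = "half_reaction")
}

#' @export
print.half_reaction <- function(x, ...) {
  fmt <- function(side) paste(
    sprintf("%s %s", ifelse(side == 1, "", side), names(side)), collapse = " + ")
  cat(sprintf("<half_reaction> %s + %d e- -> %s\n",
              fmt(x$oxidized_side), x$n_electrons, fmt(x$reduced_side)))
  invisible(x)
}

#' Library of standard half reactions
#'
#' @param name One of `"lactate/CO2"` (12 e-), `"formate/CO2"` (2 e-),
#'   `"acetate/CO2"` (8 e-), `"nitrate/nitrite"` (2 e-),
#'   `"nitrite/ammonium"` (6 e-), `"nitrite/NO"` (1 e-),
#'   `"NO/N2O"` (2 e-), `"nitrite/N2O"` (4 e-), `"N2O/N2"` (2 e-).
#'   Named donor couples are stored in the reduction direction like all
#'   half reactions; pass them as `donor_ox` to run them in oxidation.
#' @param table A [thermo_table()].
#' @return A [half_reaction()].
#' @export
std_half_reaction <- function(name, table = default_thermo_table()) {
  defs <- list(
    "lactate/CO2"      = list(c(CO2 = 3),     c(lactate = 1),  12L),
    "formate/CO2"      = list(c(CO2 = 1),     c(formate = 1),   2L),
    "acetate/CO2"      = list(c(CO2 = 2),     c(acetate = 1),   8L),
    "nitrate/nitrite"  = list(c(nitrate = 1), c(nitrite = 1),   2L),
    "nitrite/ammonium" = list(c(nitrite = 1), c(ammonium = 1),  6L),
    "nitrite/NO"       = list(c(nitrite = 1), c(NO = 1),        1L),
    "NO/N2O"           = list(c(NO = 2),      c(N2O = 1),       2L),
    "nitrite/N2O"      = list(c(nitrite = 2), c(N2O = 1),       4L),
    "N2O/N2"           = list(c(N2O = 1),     c(N2 = 1),        2L)
  )
  d <- defs[[name]]
  if (is.null(d))
    stopf("unknown half reaction '%s' (available: %s)",
          name, paste(names(defs), collapse = ", "))
  half_reaction(d[[1]], d[[2]], d[[3]], table = table)
}

merge_coeffs <- function(...) {
  sides <- list(...)
  out <- numeric(0)
  for (s in sides)
    for (nm in names(s)) out[nm] <- num_get(out, nm) + s[[nm]]
  out[abs(out) > 1e-9]
}

#' Couple a donor oxidation with an acceptor reduction
#'
#' Scales both half reactions to the least common multiple of their electron
#' counts, cancels the electrons, merges the implied H+/H2O and reduces the
#' result to smallest integer coefficients. Element and charge conservation
#' are asserted exactly; violation is an internal error, never a silent
#' return.
#'
#' @param donor_ox [half_reaction()] run in the oxidation direction (its
#'   reduced side is consumed).
#' @param acceptor_red [half_reaction()] run in the reduction direction.
#' @param table A [thermo_table()] for validation.
#' @return A `balanced_reaction`: named `coefficients` vector (negative =
#'   consumed), `n_electrons_transferred`, `reference` species names.
#' @export
#' @examples
#' r <- couple_half_reactions(std_half_reaction("lactate/CO2"),
#'                            std_half_reaction("nitrite/ammonium"))
#' r$coefficients  # lactate -1, nitrite -2, ...
couple_half_reactions <- function(donor_ox, acceptor_red,
                                  table = default_thermo_table()) {
  stopifnot(inherits(donor_ox, "half_reaction"),
            inherits(acceptor_red, "half_reaction"))
  nd <- donor_ox$n_electrons; na <- acceptor_red$n_electrons
  if (nd <= 0 || na <= 0) stopf("half reactions must transfer > 0 electrons")
  L <- lcm2(nd, na)
  sd <- L / nd; sa <- L / na
  coeffs <- merge_coeffs(
    sd * donor_ox$oxidized_side,  -sd * donor_ox$reduced_side,
    -sa * acceptor_red$oxidized_side, sa * acceptor_red$reduced_side
  )
  ne <- L
  if (length(coeffs) > 0) {
    g <- gcd_vec(round(coeffs))
    if (g > 1) { coeffs <- coeffs / g; ne <- L / g }
  }
  rxn <- structure(list(
    coefficients = coeffs,
    n_electrons_transferred = ne,
    reference = list(donor = names(donor_ox$reduced_side)[1],
                     acceptor = names(acceptor_red$oxidized_side)[1])
  ), class = "balanced_reaction")
  validate_balanced_reaction(rxn, table)
  rxn
}

# Internal assertion: exact element and charge conservation.
validate_balanced_reaction <- function(rxn, table) {
  nm <- names(rxn$coefficients)
  if (length(nm) == 0L) return(invisible(rxn))  # null reaction
  formulas <- lapply(stats::setNames(nm, nm),
                     function(n) lookup_species(table, n))
  totals <- numeric(0)
  for (n in nm) {
    f <- formulas[[n]]$formula
    for (el in names(f))
      totals[el] <- num_get(totals, el) + rxn$coefficients[[n]] * f[[el]]
  }
  if (any(abs(totals) > 1e-9))
    stop(sprintf("internal error: element imbalance after merge (%s)",
                 paste(names(totals)[abs(totals) > 1e-9], collapse = ", ")))
  q <- sum(vapply(nm, function(n) rxn$coefficients[[n]] * formulas[[n]]$charge, 0))
  if (abs(q) > 1e-9)
    stop("internal error: charge imbalance after merge")
  invisible(rxn)
}

#' @export
print.balanced_reaction <- function(x, ...) {
  co <- x$coefficients
  lhs <- co[co < 0]; rhs <- co[co > 0]
  fmt <- function(v) paste(
    sprintf("%s%s", ifelse(abs(v) == 1, "", paste0(abs(v), " ")), names(v)),
    collapse = " + ")
  cat(sprintf("<balanced_reaction> %s -> %s  (%d e-)\n",
              fmt(lhs), fmt(rhs), x$n_electrons_transferred))
  invisible(x)
}

#' Biochemical-standard Gibbs free energy of a balanced reaction
#'
#' Delta G standard-prime is the coefficient-weighted sum of formation
#' energies, with the proton term corrected to the table's pH
#' (-RT ln 10 * pH per proton). Returned per formula unit of the reaction
#' as written, with an itemized term list in the `"terms"` attribute.
#'
#' @param reaction A [couple_half_reactions()] result.
#' @param table A [thermo_table()]; every reaction species must be present.
#' @return Numeric, kJ per formula unit, with attributes `terms`
#'   (data.frame) and `provenance`.
#' @export
gibbs_free_energy <- function(reaction, table = default_thermo_table()) {
  stopifnot(inherits(reaction, "balanced_reaction"))
  co <- reaction$coefficients
  if (length(co) == 0L) {
    out <- 0
    attr(out, "terms") <- data.frame(species = character(), coefficient = numeric(),
                                     dGf_prime = numeric(), term = numeric())
    attr(out, "provenance") <- table$provenance
    return(out)
  }
  dgf <- vapply(names(co), function(nm) dgf_effective(table, nm), 0)
  terms <- data.frame(species = names(co), coefficient = unname(co),
                      dGf_prime = unname(dgf), term = unname(co * dgf),
                      stringsAsFactors = FALSE)
  out <- sum(terms$term)
  attr(out, "terms") <- terms
  attr(out, "provenance") <- table$provenance
  out
}

#' Normalize a reaction Delta G to a per-mole basis
#'
#' @param reaction A `balanced_reaction`.
#' @param dG Total Delta G for the reaction as written (kJ); if missing it
#'   is computed from `table`.
#' @param basis `"per_nitrite"`, `"per_electron"` or `"per_donor"`.
#' @param table Used only when `dG` is missing.
#' @return kJ per mole of the basis quantity.
#' @export
normalize_energy <- function(reaction, dG = NULL,
                             basis = c("per_nitrite", "per_electron", "per_donor"),
                             table = default_thermo_table()) {
  basis <- match.arg(basis)
  if (is.null(dG)) dG <- as.numeric(gibbs_free_energy(reaction, table))
  div <- switch(basis,
    per_electron = reaction$n_electrons_transferred,
    per_nitrite  = abs(num_get(reaction$coefficients, "nitrite")),
    per_donor    = abs(num_get(reaction$coefficients, reaction$reference$donor))
  )
  if (is.na(div) || div == 0)
    stopf("basis '%s' has zero coefficient in this reaction", basis)
  as.numeric(dG) / div
}

#' Media recipe for C:NO3- ratio bookkeeping
#'
#' @param donor,acceptor Species names (informational).
#' @param donor_nC Carbon atoms per donor molecule (lactate: 3).
#' @param donor_mM Donor concentration, mM.
#' @param acceptor_nN Nitrogen atoms per acceptor molecule (nitrate: 1).
#' @param acceptor_mM Acceptor concentration, mM.
#' @return A `media_recipe` list.
#' @export
media_recipe <- function(donor = "lactate", donor_nC = 3, donor_mM,
                         acceptor = "nitrate", acceptor_nN = 1, acceptor_mM) {
  assert_scalar_num(donor_nC, "donor_nC", lower = 1)
  assert_scalar_num(acceptor_nN, "acceptor_nN", lower = 1)
  assert_scalar_num(donor_mM, "donor_mM", lower = 0)
  assert_scalar_num(acceptor_mM, "acceptor_mM", lower = 0)
  structure(list(donor = donor, donor_nC = donor_nC, donor_mM = donor_mM,
                 acceptor = acceptor, acceptor_nN = acceptor_nN,
                 acceptor_mM = acceptor_mM),
            class = "media_recipe")
}

#' C:NO3- ratio of a media recipe
#'
#' The ratio of electron-donor carbon atoms to electron-acceptor nitrogen
#' atoms supplied by the medium: carbon atoms per donor molecule times donor
#' concentration, divided by nitrogen atoms per acceptor molecule times
#' acceptor concentration.
#'
#' @param recipe A [media_recipe()].
#' @return Dimensionless ratio.
#' @export
#' @examples
#' c_to_no3_ratio(media_recipe(donor_mM = 8, acceptor_mM = 12))  # 2
c_to_no3_ratio <- function(recipe) {
  stopifnot(inherits(recipe, "media_recipe"))
  if (recipe$acceptor_mM <= 0)
    stopf("acceptor concentration must be > 0 to form a C:NO3- ratio")
  (recipe$donor_nC * recipe$donor_mM) /
    (recipe$acceptor_nN * recipe$acceptor_mM)
}
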