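# Formation-energy tables for biochemical-standard Gibbs energy calculations.
#
# A thermo_table maps species names to chemical formulas, charges and
# standard Gibbs free energies of formation (kJ/mol). The proton is a
# special species: its formation energy is taken as 0 in the table and its
# contribution is corrected at evaluation time to the table's pH via
# -RT ln(10) * pH, which converts chemical-standard Delta G to the
# biochemical standard state (pH 7 by default).

GAS_CONSTANT_KJ <- 8.31446e-3  # kJ / (mol K)

parse_formula <- function(formula) {
  if (is.numeric(formula)) return(formula)  # already a named count vector
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (length(parts) == 0L || paste(parts, collapse = "") != formula)
    stopf("cannot parse chemical formula '%s'", formula)
  els <- sub("[0-9]*$", "", parts)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", parts),
                           sub("^[A-Za-z]+", "", parts), "1"))
  out <- tapply(cnt, els, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Construct a chemical species entry
#'
#' @param name Species name used in reactions (e.g. "nitrite").
#' @param formula Chemical formula string (e.g. "NO2") or named count vector.
#' @param charge Integer net charge.
#' @param dGf_prime Standard Gibbs free energy of formation, kJ/mol, at the
#'   table's reference state (protons excluded; see [thermo_table()]).
#' @param phase `"aq"` or `"g"`.
#' @return A `chemical_species` list.
#' @export
chemical_species <- function(name, formula, charge, dGf_prime, phase = "aq") {
  f <- parse_formula(formula)
  if (any(f <= 0)) stopf("species '%s': formula counts must be positive", name)
  structure(list(name = name, formula = f, charge = as.integer(charge),
                 dGf_prime = dGf_prime, phase = phase),
            class = "chemical_species")
}

#' Assemble a formation-energy table
#'
#' @param species List of [chemical_species()] entries.
#' @param provenance Free-text provenance string; recorded in every report
#'   because computed Delta-G values depend on the table used.
#' @param temperature Temperature in kelvin.
#' @param pH pH of the biochemical standard state.
#' @return A `thermo_table` object.
#' @export
thermo_table <- function(species, provenance, temperature = 298.15, pH = 7) {
  names(species) <- vapply(species, `[[`, "", "name")
  structure(list(species = species, provenance = provenance,
                 temperature = temperature, pH = pH),
            class = "thermo_table")
}

#' @export
print.thermo_table <- function(x, ...) {
  cat(sprintf("<thermo_table> %d species, %g K, pH %g\n  provenance: %s\n",
              length(x$species), x$temperature, x$pH, x$provenance))
  invisible(x)
}

lookup_species <- function(table, name) {
  sp <- table$species[[name]]
  if (is.null(sp)) stopf("species '%s' not found in thermo table", name)
  sp
}

# Effective formation energy: the proton picks up the pH correction term.
dgf_effective <- function(table, name) {
  sp <- lookup_species(table, name)
  if (name == "H+")
    return(-GAS_CONSTANT_KJ * table$temperature * log(10) * table$pH)
  sp$dGf_prime
}

#' Default formation-energy table (Thauer-style, 25 degrees C)
#'
#' Standard Gibbs free energies of formation for the species used in
#' anaerobic lactate/nitrogen catabolism, transcribed from the classical
#' anaerobic-microbiology compilation of Thauer, Jungermann and Decker
#' (1977). CO2 and the nitrogen gases are tabulated as gaseous species;
#' dissolved alternatives (HCO3-) are included. The proton carries 0 here
#' and is corrected to the table pH at evaluation time.
#'
#' @param pH pH of the biochemical standard state (default 7).
#' @return A [thermo_table()].
#' @export
default_thermo_table <- function(pH = 7) {
  thermo_table(
    list(
      chemical_species("lactate",   "C3H5O3", -1L, -517.81),
      chemical_species("pyruvate",  "C3H3O3", -1L, -474.63),
      chemical_species("acetate",   "C2H3O2", -1L, -369.41),
      chemical_species("formate",   "CHO2",   -1L, -351.04),
      chemical_species("CO2",       "CO2",     0L, -394.36, phase = "g"),
      chemical_species("HCO3-",     "CHO3",   -1L, -586.85),
      chemical_species("nitrate",   "NO3",    -1L, -111.34),
      chemical_species("nitrite",   "NO2",    -1L,  -37.20),
      chemical_species("NO",        "NO",      0L,   86.57, phase = "g"),
      chemical_species("N2O",       "N2O",     0L,  104.18, phase = "g"),
      chemical_species("N2",        "N2",      0L,    0.00, phase = "g"),
      chemical_species("ammonium",  "NH4",     1L,  -79.37),
      chemical_species("H2O",       "H2O",     0L, -237.17),
      chemical_species("H2",        "H2",      0L,    0.00, phase = "g"),
      chemical_species("H+",        "H",       1L,    0.00)
    ),
    provenance = "Thauer/Jungermann/Decker 1977 compilation, gaseous CO2 and N oxides, pH correction applied to H+ only",
    temperature = 298.15, pH = pH
  )
}

#' Read a formation-energy table from YAML or JSON
#'
#' Expected structure: top-level `provenance`, `temperature`, `pH` and a
#' `species` list of records with `name`, `formula`, `charge`, `dGf_prime`
#' and optional `phase`.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A [thermo_table()].
#' @export
read_thermo_table <- function(path) {
  raw <- read_structured(path)
  if (is.null(raw$species)) stopf("thermo table file '%s' has no species list", path)
  species <- lapply(raw$species, function(s)
    chemical_species(s$name, s$formula, s$charge, s$dGf_prime,
                     s$phase %||% "aq"))
  thermo_table(species,
               provenance = raw$provenance %||% paste("file:", path),
               temperature = raw$temperature %||% 298.15,
               pH = raw$pH %||% 7)
}

# Shared loader for YAML/JSON configuration files.
read_structured <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    stopf("unsupported config format '%s' (use .yaml/.yml/.json)", ext)
  }
}
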