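# Periplasmic proton bookkeeping for branched, menaquinone-based electron
# transport chains.
#
# The ledger follows the field's back-of-the-envelope accounting: each
# quinol (MKH2) carries 2 electrons, so a pathway consuming E electrons per
# nitrite turns over E/2 quinols per nitrite. Modules credit protons
# translocated per quinol (proton pumps and Q-loops), credit protons
# released into the periplasm per quinol at quinol-oxidation sites, and
# debit protons consumed in the periplasm per catalytic turnover. A
# negative per-reaction consumption is a flat per-turnover credit (used for
# formate dehydrogenase, whose periplasmic formate oxidation contributes a
# fixed 2 H+ per nitrite turnover).
#
# Note the accounting is per printed-module arithmetic, not a strict
# electron-flux split: a chain where one quinol passes both the NADH
# dehydrogenase and the bc1 complex credits both modules with the full
# quinol flux, exactly as the published ledgers do.

MODULE_SCOPES <- c("quinol_generation", "nitrate", "nitrite_to_no",
                   "no_to_n2o", "nitrite_to_nh4")

#' Define an electron-transport-chain module
#'
#' @param name Module name (e.g. "NADH dehydrogenase", "NrfA").
#' @param scope Which step the module serves: one of
#'   `"quinol_generation"`, `"nitrate"`, `"nitrite_to_no"`, `"no_to_n2o"`,
#'   `"nitrite_to_nh4"`.
#' @param h_translocated_per_quinol H+ moved across the membrane per MKH2
#'   handled by this module.
#' @param h_released_periplasm_per_quinol H+ liberated on the periplasmic
#'   side per MKH2 oxidized at this module's quinol site.
#' @param h_consumed_periplasm_per_reaction H+ consumed in the periplasm per
#'   catalytic turnover (per nitrite for nitrite-scoped steps); negative
#'   values are flat per-turnover credits.
#' @param quinol_fraction Fraction of the chain's quinol flux handled by
#'   this module (default 1).
#' @return An `etc_module` list.
#' @export
etc_module <- function(name, scope,
                       h_translocated_per_quinol = 0,
                       h_released_periplasm_per_quinol = 0,
                       h_consumed_periplasm_per_reaction = 0,
                       quinol_fraction = 1) {
  scope <- match.arg(scope, MODULE_SCOPES)
  for (v in c(h_translocated_per_quinol, h_released_periplasm_per_quinol,
              h_consumed_periplasm_per_reaction)) {
    if (!is.finite(v) || v < -4 || v > 12)
      stopf("module '%s': proton counts must lie in [-4, 12]", name)
  }
  assert_scalar_num(quinol_fraction, "quinol_fraction", 0, 1)
  structure(list(
    name = name, scope = scope,
    h_translocated_per_quinol = h_translocated_per_quinol,
    h_released_periplasm_per_quinol = h_released_periplasm_per_quinol,
    h_consumed_periplasm_per_reaction = h_consumed_periplasm_per_reaction,
    quinol_fraction = quinol_fraction
  ), class = "etc_module")
}

#' Assemble a chain configuration
#'
#' @param pathway `"denitrification"` or `"ammonification"` (free text
#'   allowed for hypothetical chains).
#' @param modules List of [etc_module()]s.
#' @param electrons_per_nitrite Electrons consumed per nitrite by the
#'   pathway (2 for nitrite -> half-N2O as configured here, 6 for
#'   nitrite -> ammonium). Each quinol carries 2 electrons.
#' @return A `chain_config` object.
#' @export
chain_config <- function(pathway, modules, electrons_per_nitrite) {
  assert_scalar_num(electrons_per_nitrite, "electrons_per_nitrite", lower = 0)
  stopifnot(all(vapply(modules, inherits, TRUE, "etc_module")))
  names(modules) <- vapply(modules, `[[`, "", "name")
  if (anyDuplicated(names(modules)))
    stopf("duplicate module names in chain config")
  structure(list(pathway = pathway, modules = modules,
                 electrons_per_nitrite = electrons_per_nitrite,
                 electrons_per_quinol = 2L),
            class = "chain_config")
}

#' Quinols needed to carry a number of electrons
#'
#' Each quinol (MKH2) carries two electrons, so the count may be
#' half-integral (e.g. the one-electron nitrite -> NO step needs half a
#' quinol).
#'
#' @param n_electrons Electron count, >= 0.
#' @return `n_electrons / 2`.
#' @export
#' @examples
#' quinols_required(6)  # 3 MKH2 for nitrite -> ammonium
quinols_required <- function(n_electrons) {
  assert_scalar_num(n_electrons, "n_electrons", lower = 0)
  n_electrons / 2
}

#' Tally the periplasmic proton ledger of a chain
#'
#' For every module: credits `h_translocated_per_quinol` and
#' `h_released_periplasm_per_quinol` times the module's quinol flux per
#' nitrite, and debits `h_consumed_periplasm_per_reaction` once per nitrite
#' turnover. The nitrate-reduction step is shared by both pathways and is
#' excluded from per-nitrite ledgers unless `include_nitrate = TRUE`.
#'
#' @param config A [chain_config()].
#' @param include_nitrate Include modules with scope `"nitrate"`.
#' @return A `proton_ledger`: data.frame of itemized entries plus fields
#'   `gross_translocated`, `total_consumed`, `net_per_nitrite`,
#'   `quinols_per_nitrite`.
#' @export
tally_ledger <- function(config, include_nitrate = FALSE) {
  stopifnot(inherits(config, "chain_config"))
  quinols <- quinols_required(config$electrons_per_nitrite)
  rows <- list()
  for (m in config$modules) {
    if (m$scope == "nitrate" && !include_nitrate) next
    q <- quinols * m$quinol_fraction
    if (m$h_translocated_per_quinol != 0)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m$name, step = m$scope, kind = "translocated",
        h_plus = m$h_translocated_per_quinol * q)
    if (m$h_released_periplasm_per_quinol != 0)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m$name, step = m$scope, kind = "released_periplasm",
        h_plus = m$h_released_periplasm_per_quinol * q)
    if (m$h_consumed_periplasm_per_reaction != 0)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m$name, step = m$scope, kind = "consumed_periplasm",
        h_plus = -m$h_consumed_periplasm_per_reaction)
  }
  entries <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = character(), step = character(),
               kind = character(), h_plus = numeric())
  gross <- sum(entries$h_plus[entries$kind == "translocated"])
  consumed <- -sum(entries$h_plus[entries$kind == "consumed_periplasm" &
                                  entries$h_plus < 0])
  net <- sum(entries$h_plus)
  structure(list(pathway = config$pathway, entries = entries,
                 quinols_per_nitrite = quinols,
                 gross_translocated = gross, total_consumed = consumed,
                 net_per_nitrite = net),
            class = "proton_ledger")
}

#' @export
print.proton_ledger <- function(x, ...) {
  cat(sprintf("<proton_ledger> %s: %g MKH2/nitrite\n",
              x$pathway, x$quinols_per_nitrite))
  if (nrow(x$entries))
    print(x$entries, row.names = FALSE)
  cat(sprintf("  gross translocated %+g, consumed %g, net %+g H+ per nitrite\n",
              x$gross_translocated, x$total_consumed, x$net_per_nitrite))
  invisible(x)
}

#' Net proton change from swapping one module for another
#'
#' Replaces `old_module` in the config by `new_module` and returns the
#' difference in net H+ per nitrite (new minus old). Nitrate-scope modules
#' are included in the comparison, which is how the membrane-bound
#' (proton-translocating) versus periplasmic (proton-consuming) nitrate
#' reductase alternatives are scored.
#'
#' @param config A [chain_config()].
#' @param old_module Name of the module to replace.
#' @param new_module An [etc_module()] replacing it.
#' @return Numeric: change in net H+ per nitrite.
#' @export
module_swap_delta <- function(config, old_module, new_module) {
  stopifnot(inherits(config, "chain_config"), inherits(new_module, "etc_module"))
  if (!old_module %in% names(config$modules))
    stopf("module '%s' not present in chain config", old_module)
  new_cfg <- config
  new_cfg$modules[[old_module]] <- new_module
  names(new_cfg$modules)[names(new_cfg$modules) == old_module] <- new_module$name
  tally_ledger(new_cfg, include_nitrate = TRUE)$net_per_nitrite -
    tally_ledger(config, include_nitrate = TRUE)$net_per_nitrite
}

module_from_list <- function(s) {
  etc_module(
    name = s$name, scope = s$scope,
    h_translocated_per_quinol = s$h_translocated_per_quinol %||% 0,
    h_released_periplasm_per_quinol = s$h_released_periplasm_per_quinol %||% 0,
    h_consumed_periplasm_per_reaction = s$h_consumed_periplasm_per_reaction %||% 0,
    quinol_fraction = s$quinol_fraction %||% 1
  )
}

#' Read a chain configuration from YAML or JSON
#'
#' Expected keys: `pathway`, `electrons_per_nitrite` and a `modules` list
#' whose entries carry `name`, `scope` and the proton fields of
#' [etc_module()].
#'
#' @param path File path.
#' @return A [chain_config()].
#' @export
read_chain_config <- function(path) {
  raw <- read_structured(path)
  if (is.null(raw$modules)) stopf("chain config '%s' has no modules", path)
  chain_config(raw$pathway %||% "unnamed",
               lapply(raw$modules, module_from_list),
               raw$electrons_per_nitrite)
}

#' Bundled reference chain configurations
#'
#' Loads the packaged Intrasporangium calvum chain configurations whose
#' ledgers reproduce the published integers: denitrification (gross 8 H+,
#' net 6 H+ per nitrite) and respiratory ammonification (net 12 H+ per
#' nitrite, 3 MKH2 per nitrite).
#'
#' @param pathway `"denitrification"` or `"ammonification"`.
#' @return A [chain_config()].
#' @export
icalvum_chain <- function(pathway = c("denitrification", "ammonification")) {
  pathway <- match.arg(pathway)
  path <- system.file("extdata", "chains",
                      paste0("icalvum_", pathway, ".yaml"),
                      package = "nitrofate", mustWork = TRUE)
  read_chain_config(path)
}
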