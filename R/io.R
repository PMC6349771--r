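# File formats and the end-to-end pipeline runner.
#
# FASTA handling is delegated to Biostrings; CSV time series use the fixed
# schema `time_h, lactate_mM, nitrate_mM, nitrite_mM, ammonium_mM,
# n2o_umol, od600` (columns may be omitted; unknown columns are ignored
# with a warning). Reports are JSON and always embed the package version,
# seeds and thermo-table provenance.

CSV_SCHEMA <- c(time_h = "time_h", lactate = "lactate_mM",
                nitrate = "nitrate_mM", nitrite = "nitrite_mM",
                ammonium = "ammonium_mM", n2o_umol = "n2o_umol",
                od600 = "od600")

#' Read protein records from a FASTA file
#'
#' Wrapped lines and Windows line endings are tolerated; sequences are
#' upper-cased. Duplicate ids and illegal residue characters are errors.
#'
#' @param path FASTA file.
#' @param family_labels Optional: either a single label applied to all
#'   records, or a named character vector / two-column data.frame (id,
#'   label) mapping ids to family labels.
#' @return List of [protein_record()]s.
#' @export
read_fasta <- function(path, family_labels = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  # Biostrings silently drops invalid letters with a warning; promote that
  # to an error so corrupt records never pass through truncated
  aa <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stopf("illegal residue characters in FASTA file '%s'", path)
      invokeRestart("muffleWarning")
    })
  if (length(aa) == 0L) stopf("no records in FASTA file '%s'", path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids))
    stopf("duplicate ids in FASTA: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  label_for <- function(id) {
    if (is.null(family_labels)) return(NA_character_)
    if (is.data.frame(family_labels)) {
      i <- match(id, family_labels[[1]])
      return(if (is.na(i)) NA_character_ else as.character(family_labels[[2]][i]))
    }
    if (length(family_labels) == 1L && is.null(names(family_labels)))
      return(as.character(family_labels))
    i <- match(id, names(family_labels))
    if (is.na(i)) NA_character_ else as.character(family_labels[[i]])
  }
  mapply(function(id, s) protein_record(id, s, label_for(id)),
         ids, as.character(aa), SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Write protein records to a FASTA file
#'
#' @param records List of [protein_record()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a metabolite time series from CSV
#'
#' @param path CSV with a `time_h` column and any subset of the schema
#'   columns `lactate_mM, nitrate_mM, nitrite_mM, ammonium_mM, n2o_umol,
#'   od600`.
#' @param volume_ml Vessel liquid volume, mL.
#' @return A [metabolite_series()]; missing analytes are simply absent.
#' @export
read_timeseries_csv <- function(path, volume_ml) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = TRUE)
  if (!"time_h" %in% names(df)) stopf("CSV '%s' lacks the time_h column", path)
  known <- unname(CSV_SCHEMA)
  extra <- setdiff(names(df), known)
  if (length(extra))
    warnf("ignoring unknown columns in '%s': %s", path,
          paste(extra, collapse = ", "))
  if (any(diff(df$time_h) <= 0))
    stopf("time_h must be strictly increasing in '%s'", path)
  tracks <- list()
  for (key in names(CSV_SCHEMA)) {
    col <- CSV_SCHEMA[[key]]
    if (key == "time_h" || !col %in% names(df)) next
    v <- df[[col]]
    if (any(v < 0, na.rm = TRUE))
      stopf("negative values in column %s of '%s'", col, path)
    tracks[[key]] <- v
  }
  metabolite_series(df$time_h, tracks, volume_ml)
}

#' Write a metabolite series to CSV in the standard schema
#'
#' @param series A [metabolite_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(series, path) {
  df <- data.frame(time_h = series$time_h)
  for (key in names(series$tracks)) {
    col <- CSV_SCHEMA[[key]] %||% key
    df[[col]] <- series$tracks[[key]]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a per-protein ARSC table as TSV
#'
#' Columns: id, length, n_counted, c_arsc, n_arsc, o_arsc, s_arsc.
#'
#' @param proteins List of [protein_record()]s.
#' @param path Output path.
#' @param ambiguity_policy Passed to [compute_arsc()].
#' @return The table, invisibly.
#' @export
write_arsc_tsv <- function(proteins, path,
                           ambiguity_policy = c("drop", "strict")) {
  prof <- compute_arsc_set(proteins, ambiguity_policy = ambiguity_policy)
  prof$length <- vapply(proteins, function(p) nchar(p$sequence), 0L)
  out <- prof[, c("id", "length", "n_residues_counted",
                  "c_arsc", "n_arsc", "o_arsc", "s_arsc")]
  names(out)[3] <- "n_counted"
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}

pkg_version <- function() {
  as.character(utils::packageVersion("nitrofate"))
}

#' Run the end-to-end demonstration pipeline
#'
#' Executes simulate -> partition -> thermodynamic and proton-ledger
#' summaries -> ARSC comparison on synthetic inputs, and writes a JSON run
#' report plus stage outputs (time-series CSVs, ARSC TSVs) into `out_dir`.
#' All randomness derives from `config$seed`; rerunning an identical
#' config reproduces identical deterministic report fields.
#'
#' @param config List with fields `seed` (required) and optionally
#'   `out_dir`, `ratios`, `nitrate_mM`, `noise_sigma`, `n_proteins`,
#'   `protein_length`, `delta_c_arsc`, `delta_n_arsc`, `thermo_table`
#'   (path) and `chain_dir` (path to chain YAMLs).
#' @return The run report (list), invisibly; written to
#'   `out_dir/run_report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed)) stopf("pipeline config requires a seed")
  out_dir <- config$out_dir %||% "nitrofate_run"
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  table <- stage("thermo_table", {
    if (!is.null(config$thermo_table)) read_thermo_table(config$thermo_table)
    else default_thermo_table()
  })
  chains <- stage("chain_configs", {
    if (!is.null(config$chain_dir)) {
      list(denitrification = read_chain_config(
             file.path(config$chain_dir, "icalvum_denitrification.yaml")),
           ammonification = read_chain_config(
             file.path(config$chain_dir, "icalvum_ammonification.yaml")))
    } else {
      list(denitrification = icalvum_chain("denitrification"),
           ammonification = icalvum_chain("ammonification"))
    }
  })
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # stage 1: synthetic end-point panel + per-culture partitioning
  panel <- stage("simulate", generate_endpoint_panel(
    ratios = config$ratios %||% c(4, 2, 1, 0.5, 0.1),
    nitrate_mM = config$nitrate_mM %||% c(12, 1.2),
    noise_sigma = config$noise_sigma %||% 0.02,
    seed = config$seed))
  cultures <- stage("partition", lapply(seq_along(panel$cultures), function(i) {
    sim <- panel$cultures[[i]]
    write_timeseries_csv(sim$series,
                         file.path(out_dir, sprintf("culture_%02d.csv", i)))
    an <- analyze_culture(sim$series)
    list(ratio = panel$design$ratio[i],
         nitrate_mM = panel$design$nitrate_mM[i],
         lactate_mM = panel$design$lactate_mM[i],
         c_to_no3 = c_to_no3_ratio(media_recipe(
           donor_mM = panel$design$lactate_mM[i],
           acceptor_mM = panel$design$nitrate_mM[i])),
         f_amm_true = panel$design$f_amm_true[i],
         f_amm = an$partition$f_amm,
         recovery_percent = an$recovery_percent,
         mu = if (is.null(an$growth)) NA_real_ else an$growth$mu)
  }))
  mu <- vapply(cultures, function(x) x$mu %||% NA_real_, 0)
  fa <- vapply(cultures, `[[`, 0, "f_amm")
  reg <- stage("regression", {
    ok <- is.finite(mu)
    if (sum(ok) >= 3) growth_vs_partition_regression(mu[ok], fa[ok]) else NULL
  })

  # stage 2: thermodynamic summary
  thermo <- stage("thermo", {
    lac <- std_half_reaction("lactate/CO2", table)
    amm <- couple_half_reactions(lac, std_half_reaction("nitrite/ammonium", table), table)
    den <- couple_half_reactions(lac, std_half_reaction("nitrite/N2O", table), table)
    dg_a <- gibbs_free_energy(amm, table); dg_d <- gibbs_free_energy(den, table)
    list(
      ammonification = list(
        dG_total_kJ = as.numeric(dg_a),
        dG_per_nitrite = normalize_energy(amm, as.numeric(dg_a)),
        dG_per_electron = normalize_energy(amm, as.numeric(dg_a), "per_electron")),
      denitrification = list(
        dG_total_kJ = as.numeric(dg_d),
        dG_per_nitrite = normalize_energy(den, as.numeric(dg_d)),
        dG_per_electron = normalize_energy(den, as.numeric(dg_d), "per_electron")),
      table_provenance = table$provenance)
  })

  # stage 3: proton ledgers
  ledgers <- stage("ledger", lapply(chains, function(cfg) {
    led <- tally_ledger(cfg)
    list(pathway = led$pathway, quinols_per_nitrite = led$quinols_per_nitrite,
         gross_translocated = led$gross_translocated,
         total_consumed = led$total_consumed,
         net_per_nitrite = led$net_per_nitrite)
  }))

  # stage 4: ARSC comparison on planted synthetic families
  arsc <- stage("arsc", {
    n <- config$n_proteins %||% 30L
    len <- config$protein_length %||% 300L
    base_seed <- derive_seed(config$seed, 901)
    grpA <- generate_protein_set(n, len, seed = base_seed,
                                 family_label = "nrfa_like")
    grpB <- generate_protein_set(n, len,
                                 delta_c_arsc = -(config$delta_c_arsc %||% 0.3),
                                 delta_n_arsc = -(config$delta_n_arsc %||% 0.1),
                                 seed = derive_seed(config$seed, 902),
                                 family_label = "nirk_like")
    write_arsc_tsv(c(grpA, grpB), file.path(out_dir, "arsc_profiles.tsv"))
    cmp <- compare_arsc_groups(compute_arsc_set(grpA), compute_arsc_set(grpB),
                               n_permutations = config$n_permutations %||% 2000L,
                               seed = derive_seed(config$seed, 903))
    unclass(cmp)
  })

  report <- list(
    tool = "nitrofate", version = pkg_version(),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    thermo = thermo,
    ledgers = ledgers,
    cultures = cultures,
    growth_vs_partition = if (is.null(reg)) NULL else unclass(reg),
    arsc_comparison = arsc,
    provenance = list(thermo_table = table$provenance,
                      chain_pathways = vapply(chains, `[[`, "", "pathway"))
  )
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}
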