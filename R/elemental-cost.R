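# Protein side-chain elemental cost (ARSC) statistics.
#
# ARSC ("atoms per residue side-chain") is the mean number of atoms of a
# given element carried by the side chains of a protein, i.e. total
# side-chain atoms of that element divided by the number of residues.
# Because every residue shares an identical backbone (2 C, 1 N, 2 O per
# residue in the chain), differences in ARSC isolate the elemental cost a
# protein's sequence imposes beyond the obligatory backbone, which is the
# relevant quantity when C or N limitation exerts selective pressure on
# enzyme evolution.

# Free-amino-acid molecular formulas for the 20 standard residues.
# Side-chain counts are derived, not typed in: C_side = C - 2 (Calpha +
# carbonyl), N_side = N - 1 (backbone amide). S and O side-chain counts are
# tabulated the same way (O_side = O - 2).
AA_FORMULAS <- data.frame(
  code = c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
  C = c(3L, 6L, 4L, 4L, 3L, 5L, 5L, 2L, 6L, 6L,
        6L, 6L, 5L, 9L, 5L, 3L, 4L, 11L, 9L, 5L),
  H = c(7L, 14L, 8L, 7L, 7L, 9L, 10L, 5L, 9L, 13L,
        13L, 14L, 11L, 11L, 9L, 7L, 9L, 12L, 11L, 11L),
  N = c(1L, 4L, 2L, 1L, 1L, 1L, 2L, 1L, 3L, 1L,
        1L, 2L, 1L, 1L, 1L, 1L, 1L, 2L, 1L, 1L),
  O = c(2L, 2L, 3L, 4L, 2L, 4L, 3L, 2L, 2L, 2L,
        2L, 2L, 2L, 2L, 2L, 3L, 3L, 2L, 3L, 2L),
  S = c(0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L,
        0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
  stringsAsFactors = FALSE
)

# Residue codes accepted in sequences but never counted: ambiguity codes,
# selenocysteine/pyrrolysine, stop and gap characters.
AMBIGUOUS_CODES <- c("X", "B", "Z", "J", "U", "O", "*", "-", ".")

#' Side-chain atom composition table
#'
#' Returns the built-in table of side-chain atom counts for the 20 standard
#' amino acids, derived from their free-amino-acid molecular formulas by
#' subtracting the invariant backbone atoms (2 C, 1 N, 2 O per residue).
#'
#' @return A data.frame with columns `code`, `sidechain_C`, `sidechain_N`,
#'   `sidechain_O`, `sidechain_S` and the full-formula columns
#'   `C`, `H`, `N`, `O`, `S`.
#' @export
#' @examples
#' sidechain_table()
sidechain_table <- function() {
  tab <- AA_FORMULAS
  tab$sidechain_C <- tab$C - 2L
  tab$sidechain_N <- tab$N - 1L
  tab$sidechain_O <- tab$O - 2L
  tab$sidechain_S <- tab$S
  tab[, c("code", "sidechain_C", "sidechain_N", "sidechain_O", "sidechain_S",
          "C", "H", "N", "O", "S")]
}

#' Side-chain C and N atom counts for one residue
#'
#' @param residue_code Single one-letter amino-acid code (upper case).
#' @return Named numeric vector `c(sidechain_C = , sidechain_N = )`.
#' @export
#' @examples
#' sidechain_composition("K")  # lysine: 4 C, 1 N
sidechain_composition <- function(residue_code) {
  if (!is.character(residue_code) || length(residue_code) != 1L)
    stopf("residue_code must be a single character")
  tab <- sidechain_table()
  i <- match(toupper(residue_code), tab$code)
  if (is.na(i))
    stopf("'%s' is not a standard residue", residue_code)
  c(sidechain_C = tab$sidechain_C[i], sidechain_N = tab$sidechain_N[i])
}

#' Construct a validated protein record
#'
#' @param id Sequence identifier.
#' @param sequence Amino-acid string; upper-cased on input. Only the 20
#'   standard codes plus the ambiguity set (X, B, Z, J, U, O, `*`, `-`, `.`)
#'   are allowed.
#' @param family_label Optional free-text group tag (e.g. "NrfA", "NirK").
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, family_label = NA_character_) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stopf("sequence must be a non-empty string (record '%s')", id)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  allowed <- c(AA_FORMULAS$code, AMBIGUOUS_CODES)
  bad <- setdiff(unique(chars), allowed)
  if (length(bad) > 0L)
    stopf("record '%s' contains illegal residue characters: %s",
          id, paste(bad, collapse = ", "))
  structure(
    list(id = as.character(id), sequence = sequence,
         family_label = as.character(family_label)),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s [%s], %d aa\n",
              x$id, x$family_label, nchar(x$sequence)))
  invisible(x)
}

#' Compute atoms per residue side-chain (ARSC) for one protein
#'
#' `c_arsc` is the mean side-chain carbon count per counted residue and
#' `n_arsc` the analogous nitrogen count, i.e. elemental composition
#' normalised to protein length. Sulfur and oxygen ARSC are reported as
#' well.
#'
#' @param protein A `protein_record`, or a plain string (coerced with a
#'   generated id).
#' @param ambiguity_policy `"drop"` (default) removes ambiguity codes and
#'   gaps from both numerator and denominator; `"strict"` errors on any
#'   non-standard residue.
#' @return An object of class `arsc_profile`: a one-row data.frame with
#'   columns `id`, `n_residues_counted`, `c_arsc`, `n_arsc`, `o_arsc`,
#'   `s_arsc`.
#' @export
#' @examples
#' compute_arsc(protein_record("toy", "KR"))  # c_arsc 4, n_arsc 2
compute_arsc <- function(protein, ambiguity_policy = c("drop", "strict")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  if (is.character(protein))
    protein <- protein_record("seq1", protein)
  stopifnot(inherits(protein, "protein_record"))
  chars <- strsplit(protein$sequence, "", fixed = TRUE)[[1]]
  tab <- sidechain_table()
  idx <- match(chars, tab$code)
  if (ambiguity_policy == "strict" && anyNA(idx))
    stopf("record '%s': non-standard residues present under strict policy: %s",
          protein$id, paste(unique(chars[is.na(idx)]), collapse = ", "))
  idx <- idx[!is.na(idx)]
  n <- length(idx)
  if (n == 0L)
    stopf("record '%s': no countable residues after filtering", protein$id)
  out <- data.frame(
    id = protein$id,
    n_residues_counted = n,
    c_arsc = sum(tab$sidechain_C[idx]) / n,
    n_arsc = sum(tab$sidechain_N[idx]) / n,
    o_arsc = sum(tab$sidechain_O[idx]) / n,
    s_arsc = sum(tab$sidechain_S[idx]) / n,
    stringsAsFactors = FALSE
  )
  class(out) <- c("arsc_profile", class(out))
  out
}

#' ARSC profiles for a list of proteins
#'
#' @param proteins List of `protein_record` objects (e.g. from
#'   [read_fasta()]).
#' @inheritParams compute_arsc
#' @return A data.frame with one `arsc_profile` row per protein.
#' @export
compute_arsc_set <- function(proteins, ambiguity_policy = c("drop", "strict")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  rows <- lapply(proteins, compute_arsc, ambiguity_policy = ambiguity_policy)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Mean difference of a statistic between the first nA labels and the rest.
mean_diff_stat <- function(values, is_a) {
  mean(values[is_a]) - mean(values[!is_a])
}

#' Compare ARSC between two protein families
#'
#' Tests whether group A and group B differ in mean per-protein C-ARSC and
#' N-ARSC. Two complementary tests are reported for each element: a Welch
#' two-sample t-test, and a label-permutation test of the two-sided tail
#' probability of the observed mean difference. With `exact = TRUE` (or
#' automatically when the total group size is at most 10) all label splits
#' are enumerated, making the permutation p-value the exact tail fraction.
#'
#' @param groupA,groupB data.frames of ARSC profiles ([compute_arsc_set()]),
#'   each with at least 2 rows.
#' @param n_permutations Number of random label permutations (ignored when
#'   enumerating). Sampled p-values lie in `[1/(n_permutations+1), 1]`.
#' @param seed Integer seed; mandatory for reproducibility.
#' @param exact Force complete enumeration of label assignments.
#' @return An object of class `arsc_comparison` (a list) with fields
#'   `mean_diff_C`, `mean_diff_N`, `t_statistic_C`, `t_statistic_N`,
#'   `p_welch_C`, `p_welch_N`, `p_perm_C`, `p_perm_N`, `n_permutations`,
#'   `exact`, `seed`, `n_A`, `n_B`.
#' @export
compare_arsc_groups <- function(groupA, groupB, n_permutations = 10000L,
                                seed, exact = FALSE) {
  if (missing(seed)) stopf("seed is required for compare_arsc_groups")
  nA <- nrow(groupA); nB <- nrow(groupB)
  if (is.null(nA) || is.null(nB) || nA < 2L || nB < 2L)
    stopf("insufficient group size: each group needs >= 2 profiles")
  n <- nA + nB
  cvals <- c(groupA$c_arsc, groupB$c_arsc)
  nvals <- c(groupA$n_arsc, groupB$n_arsc)
  is_a <- seq_len(n) <= nA

  obs_c <- mean_diff_stat(cvals, is_a)
  obs_n <- mean_diff_stat(nvals, is_a)

  welch <- function(vals) {
    # degenerate zero-variance groups: t-test undefined, fall back to NA
    if (stats::var(vals[is_a]) == 0 && stats::var(vals[!is_a]) == 0)
      return(list(statistic = if (obs_any(vals)) Inf else 0, p.value = NA_real_))
    tt <- stats::t.test(vals[is_a], vals[!is_a], var.equal = FALSE)
    list(statistic = unname(tt$statistic), p.value = tt$p.value)
  }
  obs_any <- function(vals) mean_diff_stat(vals, is_a) != 0

  wc <- welch(cvals)
  wn <- welch(nvals)

  enumerate <- exact || n <= 10L
  if (enumerate) {
    splits <- utils::combn(n, nA)
    n_perm <- ncol(splits)
    perm_p <- function(vals, obs) {
      diffs <- apply(splits, 2L, function(ix) {
        sel <- logical(n); sel[ix] <- TRUE
        mean_diff_stat(vals, sel)
      })
      mean(abs(diffs) >= abs(obs) - 1e-12)
    }
    p_perm_c <- perm_p(cvals, obs_c)
    p_perm_n <- perm_p(nvals, obs_n)
  } else {
    n_perm <- as.integer(n_permutations)
    if (n_perm < 1L) stopf("n_permutations must be >= 1")
    set.seed(seed)
    perm_p <- function(vals, obs) {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        sel <- logical(n); sel[sample.int(n, nA)] <- TRUE
        if (abs(mean_diff_stat(vals, sel)) >= abs(obs) - 1e-12) hits <- hits + 1L
      }
      (hits + 1L) / (n_perm + 1L)
    }
    p_perm_c <- perm_p(cvals, obs_c)
    p_perm_n <- perm_p(nvals, obs_n)
  }

  structure(list(
    mean_diff_C = obs_c, mean_diff_N = obs_n,
    t_statistic_C = wc$statistic, t_statistic_N = wn$statistic,
    p_welch_C = wc$p.value, p_welch_N = wn$p.value,
    p_perm_C = p_perm_c, p_perm_N = p_perm_n,
    n_permutations = n_perm, exact = enumerate,
    seed = seed, n_A = nA, n_B = nB
  ), class = "arsc_comparison")
}

#' @export
print.arsc_comparison <- function(x, ...) {
  cat(sprintf("<arsc_comparison> A (n=%d) vs B (n=%d)\n", x$n_A, x$n_B))
  cat(sprintf("  C-ARSC: diff %+0.4f  t = %0.2f  p_welch = %.3g  p_perm = %.3g\n",
              x$mean_diff_C, x$t_statistic_C, x$p_welch_C, x$p_perm_C))
  cat(sprintf("  N-ARSC: diff %+0.4f  t = %0.2f  p_welch = %.3g  p_perm = %.3g\n",
              x$mean_diff_N, x$t_statistic_N, x$p_welch_N, x$p_perm_N))
  cat(sprintf("  permutations: %d%s, seed %s\n", x$n_permutations,
              if (x$exact) " (complete enumeration)" else "", x$seed))
  invisible(x)
}
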