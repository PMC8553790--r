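# Per-protein physicochemistry: composition, average molecular weight, and
# isoelectric point from a Henderson-Hasselbalch charge model.

.aa_count_matrix <- function(sequences) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::letterFrequency(set, letters = c(AA_CANONICAL, AA_AMBIGUOUS))
}

#' Amino-acid composition of sequences
#'
#' Composition fractions are taken over canonical residues only: ambiguity
#' codes are counted in `ambiguous_count` but excluded from the denominator,
#' so the 20 fractions always sum to 1.
#'
#' @param sequence Character vector of validated residue strings.
#' @return A tibble with one row per sequence: `n_canonical`,
#'   `ambiguous_count` and the 20 fraction columns `frac_A` ... `frac_V`.
#' @export
#' @examples
#' aa_composition("MSSTT")[, c("frac_M", "frac_S", "frac_T")]
aa_composition <- function(sequence) {
  stopifnot(length(sequence) >= 1L)
  counts <- .aa_count_matrix(sequence)
  canon <- counts[, AA_CANONICAL, drop = FALSE]
  n_can <- rowSums(canon)
  n_amb <- as.integer(rowSums(counts[, AA_AMBIGUOUS, drop = FALSE]))
  if (any(n_can == 0)) {
    abort(
      paste0("Undefined composition: no canonical residues in sequence(s) ",
             "at position(s) ", paste(which(n_can == 0), collapse = ", ")),
      class = "proteomap_validation_error"
    )
  }
  frac <- canon / n_can
  colnames(frac) <- paste0("frac_", AA_CANONICAL)
  dplyr::bind_cols(
    tibble(n_canonical = as.integer(n_can), ambiguous_count = n_amb),
    as_tibble(frac)
  )
}

#' Average molecular weight of protein sequences
#'
#' Sum of average residue masses plus one water. Ambiguity codes contribute
#' the policy-defined masses of the table (see [aa_mass_table()]) under the
#' default `"average"` policy, or raise an error under `"strict"`.
#'
#' @param sequence Character vector of validated residue strings.
#' @param mass_table A mass table name or object (see [aa_mass_table()]).
#' @param ambiguity `"average"` (default) or `"strict"`.
#' @return Numeric vector of molecular weights in Da.
#' @export
#' @examples
#' molecular_weight("G")  # one glycine residue + water
molecular_weight <- function(sequence, mass_table = aa_mass_table(),
                             ambiguity = c("average", "strict")) {
  ambiguity <- match.arg(ambiguity)
  mt <- aa_mass_table(mass_table)
  counts <- .aa_count_matrix(sequence)
  n_amb <- rowSums(counts[, AA_AMBIGUOUS, drop = FALSE])
  if (ambiguity == "strict" && any(n_amb > 0)) {
    abort(
      paste0("Residue(s) without a strict mass at sequence position(s): ",
             paste(which(n_amb > 0), collapse = ", ")),
      class = "proteomap_validation_error"
    )
  }
  mw <- counts[, AA_CANONICAL, drop = FALSE] %*% mt$residue_mass[AA_CANONICAL] +
    counts[, AA_AMBIGUOUS, drop = FALSE] %*% mt$ambiguity_mass[AA_AMBIGUOUS] +
    mt$water_mass
  as.numeric(mw)
}

# Ionizable-group counts: one N-terminus, one C-terminus, plus side chains.
# Ambiguity codes contribute no ionizable groups.
.ionizable_counts <- function(sequence) {
  counts <- .aa_count_matrix(sequence)
  cbind(
    nterm = rep(1, length(sequence)),
    cterm = rep(1, length(sequence)),
    counts[, c(.ACIDIC_SIDE, .BASIC_SIDE), drop = FALSE]
  )
}

# Net charge at pH values `ph` (vector) for group-count matrix rows.
# `ph` is either length 1, length nrow(counts), or counts has 1 row.
.charge <- function(ph, counts, pk) {
  pos <- counts[, "nterm"] / (1 + 10^(ph - pk$nterm))
  for (g in .BASIC_SIDE) {
    pos <- pos + counts[, g] / (1 + 10^(ph - pk$side[[g]]))
  }
  neg <- counts[, "cterm"] / (1 + 10^(pk$cterm - ph))
  for (g in .ACIDIC_SIDE) {
    neg <- neg + counts[, g] / (1 + 10^(pk$side[[g]] - ph))
  }
  pos - neg
}

#' Net charge of a sequence across pH
#'
#' Henderson-Hasselbalch protonation model: each basic group g contributes
#' \eqn{n_g / (1 + 10^{pH - pKa_g})}, each acidic group
#' \eqn{-n_g / (1 + 10^{pKa_g - pH})}. The resulting curve is strictly
#' decreasing in pH.
#'
#' @param sequence A single validated residue string.
#' @param ph Numeric vector of pH values in `[0, 14]`.
#' @param pka_set A pKa set name or object (see [pka_set()]).
#' @return Numeric vector of net charges, one per pH value.
#' @export
#' @examples
#' net_charge("G", ph = c(3, 6.1, 9), pka_set = "emboss")
net_charge <- function(sequence, ph, pka_set = "ipc_protein") {
  stopifnot(length(sequence) == 1L, all(ph >= 0), all(ph <= 14))
  pk <- pka_set(pka_set)
  counts <- .ionizable_counts(sequence)
  counts <- counts[rep(1L, length(ph)), , drop = FALSE]
  as.numeric(.charge(ph, counts, pk))
}

#' Isoelectric point by bisection
#'
#' Finds the pH at which the net charge is zero. The charge curve is
#' continuous, positive at pH 0 and negative at pH 14 (the C-terminus is
#' always present), so a root always exists in `[0, 14]`; bisection brackets
#' it to within `tol` pH units and returns the bracket midpoint.
#'
#' @param sequence Character vector of validated residue strings.
#' @inheritParams net_charge
#' @param tol Bracket width tolerance in pH units (default `1e-3`).
#' @return Numeric vector of isoelectric points, one per sequence.
#' @export
#' @examples
#' isoelectric_point("G", pka_set = "emboss")  # midpoint of the termini pKa
isoelectric_point <- function(sequence, pka_set = "ipc_protein", tol = 1e-3) {
  stopifnot(tol > 0)
  pk <- pka_set(pka_set)
  counts <- .ionizable_counts(sequence)
  lo <- rep(0, nrow(counts))
  hi <- rep(14, nrow(counts))
  while (max(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    q <- .charge(mid, counts, pk)
    pos <- q > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  (lo + hi) / 2
}

#' Physicochemical profile of protein records
#'
#' Bundles, per record, sequence length, amino-acid composition, average
#' molecular weight and isoelectric point — the per-protein quantities that
#' all downstream aggregation, correlation and mapping operate on.
#'
#' @param data Tibble of records with columns `id` and `sequence`
#'   (`host_group` carried through when present; e.g. from [read_fasta()]).
#' @inheritParams molecular_weight
#' @inheritParams isoelectric_point
#' @return A tibble with one row per record: `id`, `host_group`, `length`,
#'   `mw_da`, `pi`, `ambiguous_count` and the 20 `frac_*` composition
#'   columns. `length` counts all residues, ambiguity codes included.
#' @export
#' @examples
#' physchem_profile(tibble::tibble(id = "p1", sequence = "MSSTT"))
physchem_profile <- function(data, pka_set = "ipc_protein",
                             mass_table = aa_mass_table(), tol = 1e-3,
                             ambiguity = c("average", "strict")) {
  stopifnot(is.data.frame(data), all(c("id", "sequence") %in% names(data)))
  ambiguity <- match.arg(ambiguity)
  if (nrow(data) == 0L) {
    abort("No records to profile.", class = "proteomap_validation_error")
  }
  ids <- data$id
  comp <- withCallingHandlers(
    aa_composition(data$sequence),
    error = function(e) {
      abort(paste0("Profiling failed: ", conditionMessage(e),
                   " [record id context: ", paste(utils::head(ids, 5), collapse = ", "), "]"),
            class = "proteomap_validation_error")
    }
  )
  out <- tibble(
    id = ids,
    host_group = if ("host_group" %in% names(data)) data$host_group
                 else rep("unassigned", nrow(data)),
    length = nchar(data$sequence),
    mw_da = molecular_weight(data$sequence, mass_table = mass_table,
                             ambiguity = ambiguity),
    pi = isoelectric_point(data$sequence, pka_set = pka_set, tol = tol),
    ambiguous_count = comp$ambiguous_count
  )
  dplyr::bind_cols(out, comp[, paste0("frac_", AA_CANONICAL)])
}
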