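# FASTA and manifest ingestion: protein records enter the pipeline here.

.aa_alphabet_rx <- function() {
  paste0("[^", paste(c(AA_CANONICAL, AA_AMBIGUOUS), collapse = ""), "]")
}

#' Read a multi-FASTA protein file into a record tibble
#'
#' Sequences are upper-cased, whitespace is removed, and a single trailing
#' stop symbol `*` (a translation artifact common in predicted proteomes) is
#' stripped. Every record is then validated against the accepted alphabet
#' (20 canonical residues plus the ambiguity codes X, B, Z, U, O, J).
#' An internal `*` is treated as a broken gene model and rejected.
#'
#' @param path Path to a FASTA file (plain or gzip-compressed).
#' @param host_group Host-group label attached to every record; one of
#'   [host_groups()] or `"unassigned"` (default).
#' @param policy Ambiguity policy, `"flag"` (keep and count non-canonical
#'   codes; default) or `"strict"` (any non-canonical code is an error).
#' @return A tibble with one row per FASTA entry, in file order: `id`,
#'   `description`, `sequence`, `host_group`, `ambiguous_count`, `ambiguity`
#'   (compact `"code:count"` summary, `""` when clean).
#' @seealso [validate_sequence()], [read_manifest()]
#' @export
#' @examples
#' fa <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 demo", "MSS", "TT"), fa)
#' read_fasta(fa)
read_fasta <- function(path, host_group = "unassigned", policy = c("flag", "strict")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "proteomap_io_error")
  }
  host_group <- .canonical_host(host_group)
  if (!host_group %in% c(host_groups(), "unassigned")) {
    abort(
      paste0("Unknown host group '", host_group, "'. Allowed: ",
             paste(c(host_groups(), "unassigned"), collapse = ", ")),
      class = "proteomap_validation_error"
    )
  }
  # BStringSet: accept any byte here so that alphabet problems surface as
  # this package's validation errors, naming the offending record.
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(gsub("\\s+", "", as.character(set)))
  seqs <- sub("\\*$", "", seqs)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort(
      paste0("Empty sequence for record(s): ",
             paste(ids[empty], collapse = ", ")),
      class = "proteomap_validation_error"
    )
  }
  records <- tibble(
    id = unname(ids),
    description = unname(desc),
    sequence = unname(seqs),
    host_group = host_group
  )
  validate_sequences(records, policy = policy)
}

#' Validate raw residue strings
#'
#' Checks a character vector of sequences against the accepted alphabet and
#' reports ambiguity-code usage. Validation is idempotent: a clean sequence
#' passes through unchanged.
#'
#' @param sequence Character vector of non-empty residue strings.
#' @param policy `"flag"` (default) keeps records containing ambiguity codes
#'   and counts them; `"strict"` raises an error naming the offending codes.
#' @return A tibble with columns `sequence`, `ambiguous_count` and
#'   `ambiguity` (e.g. `"X:2,B:1"`, or `""`).
#' @export
#' @examples
#' validate_sequence(c("MSSTT", "MXSST"))
validate_sequence <- function(sequence, policy = c("flag", "strict")) {
  policy <- match.arg(policy)
  if (length(sequence) == 0L) {
    return(tibble(sequence = character(), ambiguous_count = integer(),
                  ambiguity = character()))
  }
  if (any(is.na(sequence)) || any(!nzchar(sequence))) {
    abort("Empty sequence is not allowed.", class = "proteomap_validation_error")
  }
  sequence <- toupper(sequence)
  internal_stop <- stringr::str_detect(sequence, "\\*")
  if (any(internal_stop)) {
    abort(
      paste0("Internal stop symbol '*' in sequence(s) at position(s): ",
             paste(which(internal_stop), collapse = ", "),
             " (broken gene model)"),
      class = "proteomap_validation_error"
    )
  }
  bad <- stringr::str_detect(sequence, .aa_alphabet_rx())
  if (any(bad)) {
    chars <- unique(unlist(stringr::str_extract_all(sequence[bad], .aa_alphabet_rx())))
    abort(
      paste0("Non-alphabet character(s) ", paste(sQuote(chars), collapse = ", "),
             " in sequence(s) at position(s): ",
             paste(which(bad), collapse = ", ")),
      class = "proteomap_validation_error"
    )
  }
  amb_counts <- vapply(
    AA_AMBIGUOUS,
    function(code) stringr::str_count(sequence, stringr::fixed(code)),
    integer(length(sequence))
  )
  amb_counts <- matrix(amb_counts, nrow = length(sequence),
                       dimnames = list(NULL, AA_AMBIGUOUS))
  n_amb <- as.integer(rowSums(amb_counts))
  if (policy == "strict" && any(n_amb > 0L)) {
    offending <- which(n_amb > 0L)
    codes <- colnames(amb_counts)[colSums(amb_counts[offending, , drop = FALSE]) > 0]
    abort(
      paste0("Ambiguity code(s) ", paste(sQuote(codes), collapse = ", "),
             " rejected under strict policy (sequence position(s): ",
             paste(offending, collapse = ", "), ")"),
      class = "proteomap_validation_error"
    )
  }
  summary <- apply(amb_counts, 1L, function(cnt) {
    cnt <- cnt[cnt > 0L]
    if (!length(cnt)) "" else paste(names(cnt), cnt, sep = ":", collapse = ",")
  })
  tibble(sequence = sequence, ambiguous_count = n_amb, ambiguity = summary)
}

#' Validate the sequences of a record tibble
#'
#' Data-frame interface to [validate_sequence()]: validates the `sequence`
#' column and appends `ambiguous_count` and `ambiguity` columns.
#'
#' @param data Tibble with a `sequence` column (e.g. from [read_fasta()]).
#' @inheritParams validate_sequence
#' @return `data` with validated sequences and ambiguity columns.
#' @export
validate_sequences <- function(data, policy = c("flag", "strict")) {
  stopifnot(is.data.frame(data), "sequence" %in% names(data))
  rep <- validate_sequence(data$sequence, policy = policy)
  data$sequence <- rep$sequence
  data$ambiguous_count <- rep$ambiguous_count
  data$ambiguity <- rep$ambiguity
  as_tibble(data)
}

#' Read a host-group manifest
#'
#' A manifest is a two-column tab-separated file (no header, `#` comments
#' allowed): a FASTA path or glob pattern, and the host-group label of every
#' record in the matching file(s).
#'
#' @param path Path to the manifest TSV.
#' @return A tibble with columns `path` and `host_group` (canonicalised and
#'   validated against [host_groups()]).
#' @export
#' @examples
#' mf <- tempfile(fileext = ".tsv")
#' writeLines("algae.faa\talgae", mf)
#' read_manifest(mf)
read_manifest <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Manifest not found: ", path), class = "proteomap_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    warn("Manifest is empty: no proteome files to process.")
    return(tibble(path = character(), host_group = character()))
  }
  fields <- stringr::str_split_fixed(lines, "\t", 3L)
  if (any(!nzchar(fields[, 2L]))) {
    abort("Manifest lines must have two tab-separated columns: path<TAB>host_group.",
          class = "proteomap_validation_error")
  }
  host <- .canonical_host(fields[, 2L])
  unknown <- setdiff(unique(host), host_groups())
  if (length(unknown)) {
    abort(
      paste0("Unknown host label(s): ", paste(unknown, collapse = ", "),
             ". Allowed labels: ", paste(host_groups(), collapse = ", ")),
      class = "proteomap_validation_error"
    )
  }
  tibble(path = fields[, 1L], host_group = host)
}

#' Write records to FASTA
#'
#' @param records Tibble with `id`, `sequence` and optionally `description`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description
          else character(nrow(records))
  nm <- ifelse(!is.null(desc) & nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::AAStringSet(setNames(records$sequence, nm))
  Biostrings::writeXStringSet(set, path, width = width,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Write a host-group manifest
#'
#' @param manifest Tibble with columns `path` and `host_group`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("path", "host_group") %in% names(manifest)))
  writeLines(paste(manifest$path, manifest$host_group, sep = "\t"), path)
  invisible(path)
}
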