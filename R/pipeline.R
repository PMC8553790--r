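# End-to-end pipeline stages: synth -> profile -> report. Each stage writes
# plain-text outputs (TSV/JSON) so runs are diffable and reproducible; the
# CLI in inst/cli/proteomap is a thin wrapper over these functions.

.profile_tsv_cols <- function() {
  c("id", "host_group", "length", "mw_da", "pi", "ambiguous_count",
    paste0("frac_", AA_CANONICAL))
}

#' Profile the proteomes of a manifest
#'
#' Reads every FASTA file referenced by the manifest (paths and glob
#' patterns are resolved relative to the manifest location), validates the
#' records, computes physicochemical profiles, and optionally writes the
#' per-protein TSV. Under the `"strict"` policy, records carrying ambiguity
#' codes are skipped and reported rather than aborting the run.
#'
#' @param manifest Path to a manifest TSV ([read_manifest()]) or an
#'   equivalent tibble with `path` and `host_group` columns.
#' @param out Optional output TSV path.
#' @param policy Ambiguity policy, `"flag"` (default) or `"strict"`.
#' @param pka_set,mass_table,tol Passed to [physchem_profile()].
#' @param base_dir Directory against which relative manifest paths are
#'   resolved (defaults to the manifest's own directory, or `.`).
#' @return The profile tibble, invisibly when `out` is given.
#' @export
run_profile <- function(manifest, out = NULL, policy = c("flag", "strict"),
                        pka_set = "ipc_protein", mass_table = aa_mass_table(),
                        tol = 1e-3, base_dir = NULL) {
  policy <- match.arg(policy)
  if (is.character(manifest)) {
    base_dir <- base_dir %||% dirname(manifest)
    manifest <- read_manifest(manifest)
  } else {
    base_dir <- base_dir %||% "."
    stopifnot(is.data.frame(manifest),
              all(c("path", "host_group") %in% names(manifest)))
  }
  if (nrow(manifest) == 0L) {
    abort("Manifest resolves to no proteome files.", class = "proteomap_io_error")
  }
  records <- purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    pattern <- manifest$path[i]
    paths <- if (file.exists(file.path(base_dir, pattern))) {
      file.path(base_dir, pattern)
    } else {
      Sys.glob(file.path(base_dir, pattern))
    }
    if (!length(paths)) {
      abort(paste0("Manifest entry matches no file: ", pattern),
            class = "proteomap_io_error")
    }
    purrr::map_dfr(paths, read_fasta, host_group = manifest$host_group[i],
                   policy = "flag")
  })
  if (policy == "strict") {
    skipped <- records[records$ambiguous_count > 0L, , drop = FALSE]
    if (nrow(skipped)) {
      inform(paste0("Skipped ", nrow(skipped),
                    " record(s) with ambiguity codes under strict policy: ",
                    paste(utils::head(skipped$id, 10), collapse = ", ")))
      records <- records[records$ambiguous_count == 0L, , drop = FALSE]
    }
    if (nrow(records) == 0L) {
      abort("All records were skipped under strict policy.",
            class = "proteomap_validation_error")
    }
  }
  profiles <- physchem_profile(records, pka_set = pka_set,
                               mass_table = mass_table, tol = tol)
  inform(paste0("Profiled ", nrow(profiles), " protein(s) from ",
                nrow(manifest), " manifest entr(y/ies)."))
  if (!is.null(out)) {
    readr::write_tsv(profiles[, .profile_tsv_cols()], out)
    return(invisible(profiles))
  }
  profiles
}

.modality_entry <- function(profiles, label, bandwidth_factor, prominence_frac,
                            min_n) {
  tryCatch({
    m <- classify_modality(profiles, bandwidth_factor = bandwidth_factor,
                           prominence_frac = prominence_frac, min_n = min_n)
    list(group = label, label = m$label, pi_modes = m$pi_modes,
         mw_modes = m$mw_modes, mode_locations = round(m$mode_locations, 3),
         mw_mode_locations = round(m$mw_mode_locations, 3), n = m$n,
         parameters = m$parameters[c("bandwidth_factor", "prominence_frac")])
  }, proteomap_insufficient_data = function(e) {
    list(group = label, label = "insufficient", n = nrow(profiles))
  })
}

#' Build the full report bundle from per-protein profiles
#'
#' Writes, under `out_dir`: the per-host summary TSV, the kingdom summary
#' JSON, host and residue correlation tables, NIPALS PCA scores/loadings,
#' the pooled virtual 2D map table, per-host and pooled modality calls, the
#' effective configuration, and a checksum manifest of every file written.
#' Stages whose preconditions are not met by the data (fewer than 2 hosts
#' for host correlation, fewer than 3 for residue correlation and PCA,
#' fewer than `min_n` records for a modality call) are skipped or marked
#' rather than failing the run.
#'
#' @param profile Profile tibble or path to a per-protein TSV written by
#'   [run_profile()].
#' @param out_dir Output directory (created if missing).
#' @param neutral_tol Neutral-pI window half-width (pH units).
#' @param bandwidth_factor,prominence_frac,min_n Modality parameters
#'   (see [classify_modality()]).
#' @return Invisible list with the computed objects (`kingdom`, `host_corr`,
#'   `residue_corr`, `pca`, `map`, `modality`).
#' @export
run_report <- function(profile, out_dir, neutral_tol = 0.005,
                       bandwidth_factor = 1, prominence_frac = 0.05,
                       min_n = 50L) {
  if (is.character(profile)) {
    if (!file.exists(profile)) {
      abort(paste0("Profile TSV not found: ", profile), class = "proteomap_io_error")
    }
    profile <- readr::read_tsv(profile, show_col_types = FALSE)
  }
  stopifnot(is.data.frame(profile))
  if (nrow(profile) == 0L) {
    abort("Empty profile table: nothing to report.",
          class = "proteomap_validation_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit_tsv <- function(x, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(x, path)
    written <<- c(written, name)
  }
  emit_json <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    written <<- c(written, name)
  }

  kingdom <- summarize_kingdom(profile, neutral_tol = neutral_tol)
  emit_tsv(kingdom$hosts, "host_summary.tsv")
  emit_json(list(pooled = as.list(kingdom$pooled),
                 hosts = kingdom$hosts), "kingdom_summary.json")

  comp <- composition_matrix(kingdom)
  host_corr <- NULL
  residue_corr <- NULL
  pca <- NULL
  if (nrow(comp) >= 2L) {
    host_corr <- host_correlation(comp)
    emit_tsv(tidy(host_corr), "host_correlation.tsv")
  } else {
    inform("Single host group: host correlation skipped.")
  }
  if (nrow(comp) >= 3L) {
    residue_corr <- residue_correlation(comp)
    emit_tsv(tidy(residue_corr), "residue_correlation.tsv")
    pca <- pca_nipals(comp, n_components = min(5L, nrow(comp) - 1L))
    emit_tsv(tidy(pca, "scores"), "pca_scores.tsv")
    emit_tsv(tidy(pca, "loadings"), "pca_loadings.tsv")
    emit_tsv(tidy(pca, "variance"), "pca_variance.tsv")
  } else {
    inform("Fewer than 3 host groups: residue correlation and PCA skipped.")
  }

  map <- build_map(profile)
  emit_tsv(tidy(map), "map2d.tsv")

  hosts_present <- intersect(host_groups(), unique(profile$host_group))
  modality <- c(
    list(.modality_entry(profile, "pooled", bandwidth_factor,
                         prominence_frac, min_n)),
    lapply(hosts_present, function(h) {
      .modality_entry(profile[profile$host_group == h, , drop = FALSE], h,
                      bandwidth_factor, prominence_frac, min_n)
    })
  )
  emit_json(modality, "modality.json")

  emit_json(list(
    tool = "proteomap",
    version = as.character(utils::packageVersion("proteomap")),
    neutral_tol = neutral_tol, bandwidth_factor = bandwidth_factor,
    prominence_frac = prominence_frac, min_n = min_n
  ), "config.json")

  checksums <- tibble(
    file = written,
    md5 = unname(tools::md5sum(file.path(out_dir, written)))
  )
  readr::write_tsv(checksums, file.path(out_dir, "MANIFEST.tsv"))

  invisible(list(kingdom = kingdom, host_corr = host_corr,
                 residue_corr = residue_corr, pca = pca, map = map,
                 modality = modality))
}

# Default host label used when writing an archetype's manifest: the host
# whose proteome the archetype's modality emulates.
.archetype_host <- c(unimodal = "human", bimodal = "algae",
                     trimodal = "bacteria")

#' Generate a synthetic proteome on disk
#'
#' Samples a proteome from an archetype or an explicit spec and writes a
#' FASTA plus a matching manifest, so synthetic data flows through the same
#' entry point ([run_profile()]) as real data. Output is byte-identical for
#' identical (spec, seed).
#'
#' @param archetype Archetype label for [host_archetype()]; ignored when
#'   `spec` is given.
#' @param spec Optional [synthetic_spec()] overriding `archetype`.
#' @param n_proteins,seed Passed to [host_archetype()].
#' @param out_dir Output directory (created if missing).
#' @param host_group Host label recorded in the manifest; defaults to the
#'   host whose modality the archetype emulates (human/algae/bacteria for
#'   uni/bi/trimodal), or `"bacteria"` for a custom spec.
#' @return Invisible list with `fasta`, `manifest` paths and the `records`.
#' @export
run_synth <- function(archetype = c("unimodal", "bimodal", "trimodal"),
                      spec = NULL, n_proteins = 2000L, seed = 1L,
                      out_dir = ".", host_group = NULL) {
  if (is.null(spec)) {
    archetype <- match.arg(archetype)
    spec <- host_archetype(archetype, n_proteins = n_proteins, seed = seed)
    host_group <- host_group %||% .archetype_host[[archetype]]
  } else {
    stopifnot(inherits(spec, "synthetic_spec"))
    host_group <- host_group %||% "bacteria"
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- sample_proteome(spec)
  fasta <- file.path(out_dir, paste0(spec$name, ".faa"))
  manifest <- file.path(out_dir, paste0(spec$name, "_manifest.tsv"))
  write_proteome_fasta(records, fasta)
  write_manifest(tibble(path = basename(fasta), host_group = host_group),
                 manifest)
  inform(paste0("Wrote ", nrow(records), " synthetic protein(s) to ", fasta))
  invisible(list(fasta = fasta, manifest = manifest, records = records))
}
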