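# Host-group and kingdom-level reduction of per-protein profiles.

#' Partition profiles by isoelectric point
#'
#' Adds a `pi_class` column: `neutral` when `|pI - 7| <= neutral_tol`,
#' `acidic` below, `basic` above. The three classes are disjoint and cover
#' every profile. Bulk proteomes have almost no exactly-neutral proteins, so
#' the default window is very narrow (prints as pH 7.00).
#'
#' @param data Tibble of profiles with a `pi` column.
#' @param neutral_tol Half-width of the neutral window in pH units
#'   (default `0.005`).
#' @return `data` with a `pi_class` factor column
#'   (levels `acidic`, `neutral`, `basic`).
#' @export
#' @examples
#' partition_by_pi(tibble::tibble(pi = c(5, 7, 9)))
partition_by_pi <- function(data, neutral_tol = 0.005) {
  stopifnot(is.data.frame(data), "pi" %in% names(data), neutral_tol >= 0)
  if (nrow(data) == 0L) {
    abort("No profiles to partition.", class = "proteomap_validation_error")
  }
  cls <- dplyr::case_when(
    abs(data$pi - 7) <= neutral_tol ~ "neutral",
    data$pi < 7 - neutral_tol ~ "acidic",
    .default = "basic"
  )
  data$pi_class <- factor(cls, levels = c("acidic", "neutral", "basic"))
  as_tibble(data)
}

# One-group reduction; profiles already restricted to a single host.
.summarize_one <- function(profiles, host, neutral_tol) {
  p <- partition_by_pi(profiles, neutral_tol = neutral_tol)
  n <- nrow(p)
  frac_cols <- paste0("frac_", AA_CANONICAL)
  mean_pct <- colMeans(as.matrix(p[, frac_cols])) * 100
  names(mean_pct) <- paste0("pct_", AA_CANONICAL)
  i_long <- which.max(p$length)
  i_short <- which.min(p$length)
  i_hi <- which.max(p$pi)
  i_lo <- which.min(p$pi)
  acidic_pi <- p$pi[p$pi_class == "acidic"]
  basic_pi <- p$pi[p$pi_class == "basic"]
  dplyr::bind_cols(
    tibble(
      host_group = host,
      n_proteins = n,
      mean_length = mean(p$length),
      mean_mw_kda = mean(p$mw_da) / 1000,
      mean_pi = mean(p$pi),
      pct_acidic = 100 * sum(p$pi_class == "acidic") / n,
      pct_neutral = 100 * sum(p$pi_class == "neutral") / n,
      pct_basic = 100 * sum(p$pi_class == "basic") / n,
      acidic_mean_pi = if (length(acidic_pi)) mean(acidic_pi) else NA_real_,
      basic_mean_pi = if (length(basic_pi)) mean(basic_pi) else NA_real_
    ),
    as_tibble(as.list(mean_pct)),
    tibble(
      longest_id = p$id[i_long], longest_length = p$length[i_long],
      longest_mw_kda = p$mw_da[i_long] / 1000,
      shortest_id = p$id[i_short], shortest_length = p$length[i_short],
      max_pi_id = p$id[i_hi], max_pi = p$pi[i_hi],
      min_pi_id = p$id[i_lo], min_pi = p$pi[i_lo]
    )
  )
}

#' Summarize profiles per host group
#'
#' Unweighted arithmetic means over proteins (not over proteomes) within
#' each host group, the acidic/neutral/basic partition percentages, mean
#' composition percentages, and the extreme records (longest, shortest,
#' highest and lowest pI; ties resolved by input order). Records labelled
#' `"unassigned"` are excluded.
#'
#' @param data Profile tibble from [physchem_profile()].
#' @inheritParams partition_by_pi
#' @return A tibble with one row per host group present in `data`.
#' @export
summarize_hosts <- function(data, neutral_tol = 0.005) {
  stopifnot(is.data.frame(data), all(c("host_group", "pi", "mw_da", "length") %in% names(data)))
  data <- data[data$host_group %in% host_groups(), , drop = FALSE]
  if (nrow(data) == 0L) {
    abort("No profiles with a recognised host group.",
          class = "proteomap_validation_error")
  }
  hosts <- sort(unique(data$host_group))
  purrr::map_dfr(hosts, function(h) {
    .summarize_one(data[data$host_group == h, , drop = FALSE], h, neutral_tol)
  })
}

#' Kingdom-level summary
#'
#' Combines per-host summaries with pooled statistics over all proteins.
#' Pooled means are per-protein means over the full record set (not means of
#' host means), so hosts with more proteins weigh more — the convention for
#' reporting a collective proteome average.
#'
#' @inheritParams summarize_hosts
#' @return An object of class `kingdom_summary`: list with `hosts` (per-host
#'   tibble, see [summarize_hosts()]) and `pooled` (one-row tibble with
#'   `host_group = "all"`). `tidy()` returns the host table, `glance()` the
#'   pooled row.
#' @export
summarize_kingdom <- function(data, neutral_tol = 0.005) {
  hosts <- summarize_hosts(data, neutral_tol = neutral_tol)
  pooled_data <- data[data$host_group %in% host_groups(), , drop = FALSE]
  pooled <- .summarize_one(pooled_data, "all", neutral_tol)
  if (sum(hosts$n_proteins) != pooled$n_proteins) {
    abort("Inconsistent totals: host counts do not sum to the pooled count.",
          class = "proteomap_internal_error")
  }
  structure(
    list(hosts = hosts, pooled = pooled, neutral_tol = neutral_tol),
    class = "kingdom_summary"
  )
}

#' @export
#' @exportS3Method generics::tidy
tidy.kingdom_summary <- function(x, ...) x$hosts

#' @export
#' @exportS3Method generics::glance
glance.kingdom_summary <- function(x, ...) x$pooled

#' @export
print.kingdom_summary <- function(x, ...) {
  cat("Kingdom summary:", sum(x$hosts$n_proteins), "proteins across",
      nrow(x$hosts), "host groups\n")
  cat(sprintf("Pooled: mean length %.1f aa, mean MW %.3f kDa, mean pI %.3f\n",
              x$pooled$mean_length, x$pooled$mean_mw_kda, x$pooled$mean_pi))
  print(x$hosts[, c("host_group", "n_proteins", "mean_length",
                    "mean_mw_kda", "mean_pi")])
  invisible(x)
}

#' Rank host groups by a summary statistic
#'
#' Stable ascending sort; ties broken alphabetically by host label.
#'
#' @param summaries Per-host summary tibble ([summarize_hosts()]) or a
#'   `kingdom_summary`.
#' @param key One of `"mean_mw"`, `"mean_pi"`, `"mean_length"`.
#' @return Tibble with `host_group` and the ranked statistic, ascending.
#' @export
rank_hosts <- function(summaries, key = c("mean_mw", "mean_pi", "mean_length")) {
  key <- match.arg(key)
  if (inherits(summaries, "kingdom_summary")) summaries <- summaries$hosts
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 2L)
  col <- switch(key, mean_mw = "mean_mw_kda", mean_pi = "mean_pi",
                mean_length = "mean_length")
  out <- summaries[order(summaries[[col]], summaries$host_group), c("host_group", col)]
  as_tibble(out)
}

#' Host-by-residue composition matrix
#'
#' @param summaries Per-host summary tibble or `kingdom_summary`.
#' @return Numeric matrix, hosts in rows and the 20 residues in columns,
#'   of mean composition percentages (each row sums to 100).
#' @export
composition_matrix <- function(summaries) {
  if (inherits(summaries, "kingdom_summary")) summaries <- summaries$hosts
  pct_cols <- paste0("pct_", AA_CANONICAL)
  stopifnot(all(pct_cols %in% names(summaries)))
  m <- as.matrix(summaries[, pct_cols])
  dimnames(m) <- list(summaries$host_group, AA_CANONICAL)
  m
}
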