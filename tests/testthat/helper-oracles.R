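# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's own computation paths: character
# counting via strsplit/table, charge via a literal transcription of the
# Henderson-Hasselbalch terms, pI via exhaustive grid search, molecular
# weight via per-character accumulation, prominence via explicit
# nearest-higher-point segments.

.aa20 <- strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]]

`%||%` <- function(x, y) if (is.null(x)) y else x

random_peptide <- function(len, residues = .aa20) {
  paste(sample(residues, len, replace = TRUE), collapse = "")
}

# Expasy average residue masses, re-keyed here so the oracle does not read
# the package table.
.oracle_masses <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

# Per-character accumulation of the molecular weight.
oracle_mw <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  sum(.oracle_masses[chars]) + 18.01524
}

# Net charge at pH values `ph` (vector) for a single sequence, written
# directly from the protonation formula.
oracle_charge <- function(sequence, ph, pk) {
  chars <- strsplit(sequence, "")[[1]]
  cnt <- table(factor(chars, levels = LETTERS))
  pos <- 1 / (1 + 10^(ph - pk$nterm))
  for (g in c("H", "K", "R")) {
    pos <- pos + cnt[[g]] / (1 + 10^(ph - pk$side[[g]]))
  }
  neg <- 1 / (1 + 10^(pk$cterm - ph))
  for (g in c("D", "E", "C", "Y")) {
    neg <- neg + cnt[[g]] / (1 + 10^(pk$side[[g]] - ph))
  }
  pos - neg
}

# Exhaustive grid search for the isoelectric point at a fixed pH step.
oracle_pi_grid <- function(sequence, pka_name, step = 1e-4) {
  pk <- proteomap::pka_set(pka_name)
  ph <- seq(0, 14, by = step)
  q <- oracle_charge(sequence, ph, pk)
  ph[which.min(abs(q))]
}

# Brute-force mode counting: collapse exact plateaus, find interior local
# maxima, then take the prominence from the minima of the segments bounded
# by the nearest strictly-higher point on each side (or the boundary).
oracle_modes <- function(x, y, prominence_frac) {
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  peak_runs <- which(vapply(seq_len(k), function(i) {
    i > 1L && i < k && r$values[i] > r$values[i - 1L] &&
      r$values[i] > r$values[i + 1L]
  }, logical(1)))
  peaks <- as.integer(floor((starts[peak_runs] + ends[peak_runs]) / 2))
  if (!length(peaks)) {
    return(list(n = 0L, locations = numeric()))
  }
  proms <- vapply(peaks, function(p) {
    higher <- which(y > y[p])
    hl <- higher[higher < p]
    hr <- higher[higher > p]
    left_base <- if (length(hl)) min(y[max(hl):p]) else min(y[1:p])
    right_base <- if (length(hr)) min(y[p:min(hr)]) else min(y[p:length(y)])
    y[p] - max(left_base, right_base)
  }, numeric(1))
  keep <- proms >= prominence_frac * max(y)
  list(n = sum(keep), locations = x[peaks[keep]])
}

# Small FASTA fixture on disk; returns the path.
write_fasta_fixture <- function(lines) {
  path <- tempfile(fileext = ".faa")
  writeLines(lines, path)
  path
}
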