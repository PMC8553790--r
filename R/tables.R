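# Physical constant tables: average residue masses and ionizable-group pKa sets.

# The 20 canonical residues, in the conventional one-letter order used
# throughout the package (alphabetical by three-letter code).
AA_CANONICAL <- c(
  "A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

# Ambiguity codes retained under the default "flag" policy.
# B = Asx (N/D), Z = Glx (Q/E), J = Xle (I/L), X = unknown,
# U = selenocysteine, O = pyrrolysine.
AA_AMBIGUOUS <- c("X", "B", "Z", "U", "O", "J")

# Average (not monoisotopic) residue masses in Da, Expasy ProtParam reference
# table; residue mass = amino acid minus one water.
.AA_MASS_AVG <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

.WATER_MASS <- 18.01524

# pKa sets for the Henderson-Hasselbalch charge model.  Acidic groups:
# C-terminus, D, E, C, Y.  Basic groups: N-terminus, H, K, R.
# ipc_protein / ipc_peptide: Kozlowski (2016) Biology Direct 11:55, Table 3
#   (the optimized constants of the IPC calculator).
# emboss: defaults of the EMBOSS `iep` program.
# sillero: Sillero & Ribeiro (1989) Anal Biochem 179:319-325.
.PKA_SETS <- list(
  ipc_protein = list(
    name = "ipc_protein", nterm = 9.094, cterm = 2.869,
    side = c(C = 7.555, D = 3.872, E = 4.412, H = 5.637,
             K = 9.052, R = 11.84, Y = 10.85)
  ),
  ipc_peptide = list(
    name = "ipc_peptide", nterm = 9.564, cterm = 2.383,
    side = c(C = 8.297, D = 3.887, E = 4.317, H = 6.018,
             K = 10.517, R = 12.503, Y = 10.071)
  ),
  emboss = list(
    name = "emboss", nterm = 8.6, cterm = 3.6,
    side = c(C = 8.5, D = 3.9, E = 4.1, H = 6.5,
             K = 10.8, R = 12.5, Y = 10.1)
  ),
  sillero = list(
    name = "sillero", nterm = 8.2, cterm = 3.2,
    side = c(C = 9.0, D = 4.0, E = 4.5, H = 6.4,
             K = 10.4, R = 12.0, Y = 10.0)
  )
)

.ACIDIC_SIDE <- c("D", "E", "C", "Y")
.BASIC_SIDE <- c("H", "K", "R")

#' Names of the registered pKa sets
#'
#' @return Character vector of pKa set identifiers accepted by [pka_set()],
#'   [isoelectric_point()] and friends.
#' @export
#' @examples
#' pka_sets()
pka_sets <- function() names(.PKA_SETS)

#' Retrieve a registered pKa set
#'
#' A pKa set holds the acid-dissociation constants of the ionizable groups
#' used by the charge model: the two termini plus the side chains of
#' D, E, C, Y (acidic) and H, K, R (basic).
#'
#' @param name One of [pka_sets()]. Default `"ipc_protein"`.
#' @return A list with elements `name`, `nterm`, `cterm` and `side`
#'   (named numeric vector over C, D, E, H, K, R, Y), all in pH units.
#' @export
#' @examples
#' pka_set("emboss")$nterm
pka_set <- function(name = "ipc_protein") {
  if (is.list(name) && all(c("nterm", "cterm", "side") %in% names(name))) {
    return(name)
  }
  name <- match.arg(name, pka_sets())
  set <- .PKA_SETS[[name]]
  stopifnot(
    set$nterm > 0, set$nterm < 14, set$cterm > 0, set$cterm < 14,
    all(set$side > 0 & set$side < 14)
  )
  set
}

#' Average residue-mass table
#'
#' Masses used for bulk molecular-weight computation. Ambiguity codes carry
#' policy-defined masses: B = mean(N, D), Z = mean(Q, E), J = mean(I, L),
#' U is assigned the mass of C, O the mass of K, and X the mean of all 20
#' canonical residue masses.
#'
#' @param name Table identifier; only `"expasy_average"` is registered.
#' @return A list with `name`, `residue_mass` (named over the 20 canonical
#'   residues, Da), `ambiguity_mass` (named over X, B, Z, U, O, J, Da) and
#'   `water_mass` (Da).
#' @export
#' @examples
#' aa_mass_table()$residue_mass[["G"]]
aa_mass_table <- function(name = "expasy_average") {
  if (is.list(name) && all(c("residue_mass", "water_mass") %in% names(name))) {
    return(name)
  }
  name <- match.arg(name, "expasy_average")
  m <- .AA_MASS_AVG
  stopifnot(all(m > 0), length(m) == 20L)
  list(
    name = name,
    residue_mass = m,
    ambiguity_mass = c(
      X = mean(m),
      B = mean(m[c("N", "D")]),
      Z = mean(m[c("Q", "E")]),
      U = m[["C"]],
      O = m[["K"]],
      J = mean(m[c("I", "L")])
    ),
    water_mass = .WATER_MASS
  )
}

#' The closed host-group vocabulary
#'
#' The nine host groups used to stratify viral proteomes. Input labels are
#' canonicalised to these tokens (lower case, spaces to underscores);
#' `"unassigned"` is additionally permitted on records for library use but is
#' excluded from host-level reports.
#'
#' @return Character vector of the nine canonical host labels.
#' @export
#' @examples
#' host_groups()
host_groups <- function() {
  c("algae", "archaea", "bacteria", "fungi", "human",
    "invertebrate", "land_plant", "protozoa", "vertebrate")
}

.canonical_host <- function(x) {
  gsub("[ -]+", "_", tolower(trimws(x)))
}
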