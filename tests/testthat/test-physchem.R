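test_that("composition counts canonical residues and excludes ambiguity codes", {
  c1 <- aa_composition("MSSTT")
  expect_equal(c1$n_canonical, 5L)
  expect_equal(c1$frac_M, 0.2)
  expect_equal(c1$frac_S, 0.4)
  expect_equal(c1$frac_T, 0.4)
  expect_equal(sum(c1[paste0("frac_", .aa20)]), 1)

  c2 <- aa_composition("MXSST")
  expect_equal(c2$ambiguous_count, 1L)
  expect_equal(c2$frac_M, 0.25)
  expect_equal(c2$frac_S, 0.5)
  expect_equal(c2$frac_T, 0.25)

  c3 <- aa_composition("AAAA")
  expect_equal(c3$frac_A, 1)

  expect_error(aa_composition("XXX"), class = "proteomap_validation_error")
})

test_that("composition fractions always sum to 1 and are permutation invariant", {
  set.seed(21)
  for (i in 1:25) {
    s <- random_peptide(sample(5:400, 1))
    comp <- aa_composition(s)
    expect_equal(sum(comp[paste0("frac_", .aa20)]), 1, tolerance = 1e-12)
    perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(aa_composition(perm), comp)
    expect_equal(molecular_weight(perm), molecular_weight(s))
    expect_equal(isoelectric_point(perm), isoelectric_point(s))
  }
})

test_that("molecular weight matches hand sums and is additive", {
  # Gly residue 57.0519 Da plus one water 18.0153 Da
  expect_equal(molecular_weight("G"), 57.0519 + 18.01524, tolerance = 1e-6)
  expect_equal(molecular_weight("GG"),
               2 * 57.0519 + 18.01524, tolerance = 1e-6)
  expect_equal(molecular_weight("MSSTT"), oracle_mw("MSSTT"), tolerance = 1e-9)

  set.seed(31)
  for (i in 1:30) {
    a <- random_peptide(sample(1:200, 1))
    b <- random_peptide(sample(1:200, 1))
    expect_equal(molecular_weight(a), oracle_mw(a), tolerance = 1e-9)
    expect_equal(molecular_weight(paste0(a, b)),
                 molecular_weight(a) + molecular_weight(b) - 18.01524,
                 tolerance = 1e-9)
  }
})

test_that("ambiguity codes carry their policy-defined masses", {
  mt <- aa_mass_table()
  expect_equal(molecular_weight("B") - mt$water_mass,
               mean(c(114.1038, 115.0886)), tolerance = 1e-9)
  expect_equal(molecular_weight("Z") - mt$water_mass,
               mean(c(128.1307, 129.1155)), tolerance = 1e-9)
  expect_equal(molecular_weight("J") - mt$water_mass, 113.1594, tolerance = 1e-9)
  expect_error(molecular_weight("MXV", ambiguity = "strict"),
               class = "proteomap_validation_error")
})

test_that("net charge has the protonation limits and half-protonation points", {
  pk <- pka_set("emboss")
  # at the N-terminal pKa the N-terminus contributes exactly +0.5
  q <- net_charge("G", ph = pk$nterm, pka_set = "emboss")
  cterm_at <- -1 / (1 + 10^(pk$cterm - pk$nterm))
  expect_equal(q - cterm_at, 0.5, tolerance = 1e-9)

  set.seed(41)
  for (i in 1:20) {
    s <- random_peptide(sample(1:100, 1))
    expect_gt(net_charge(s, 0), 0)
    expect_lt(net_charge(s, 14), 0)
  }
})

test_that("net charge is strictly decreasing in pH", {
  set.seed(42)
  ph <- sort(runif(50, 0, 14))
  for (i in 1:100) {
    s <- random_peptide(sample(1:120, 1))
    q <- net_charge(s, ph)
    expect_true(all(diff(q) < 0))
  }
})

test_that("two-group peptides have the closed-form midpoint pI", {
  for (set in pka_sets()) {
    pk <- pka_set(set)
    mid <- (pk$nterm + pk$cterm) / 2
    expect_equal(isoelectric_point("G", pka_set = set), mid, tolerance = 1e-3)
    # homopolymers of non-ionizable residues: terminal groups only,
    # independent of length
    expect_equal(isoelectric_point("AAAA", pka_set = set), mid, tolerance = 1e-3)
    expect_equal(isoelectric_point(strrep("S", 200), pka_set = set), mid,
                 tolerance = 1e-3)
  }
})

test_that("bisection pI agrees with the exhaustive grid-search oracle", {
  set.seed(51)
  seqs <- vapply(sample(1:500, 40, replace = TRUE), random_peptide, character(1))
  for (set in c("ipc_protein", "emboss")) {
    got <- isoelectric_point(seqs, pka_set = set, tol = 1e-3)
    want <- vapply(seqs, oracle_pi_grid, numeric(1), pka_name = set)
    expect_lt(max(abs(got - want)), 2e-3)
  }
})

test_that("appending a basic residue never decreases pI, an acidic one never increases it", {
  set.seed(61)
  for (i in 1:20) {
    s <- random_peptide(sample(2:150, 1))
    base <- isoelectric_point(s)
    expect_gte(isoelectric_point(paste0(s, "K")) - base, -1e-3)
    expect_lte(isoelectric_point(paste0(s, "D")) - base, 1e-3)
  }
})

test_that("profiles bundle the component computations and in-text peptides", {
  rec <- tibble::tibble(
    id = c("p1", "p2", "p3"),
    sequence = c("MSSTT", "MQMQEKGWKIIIEEQ", "MGISGEKLGNFLIFK")
  )
  prof <- physchem_profile(rec)
  expect_equal(prof$length, c(5L, 15L, 15L))
  expect_equal(prof$mw_da, vapply(rec$sequence, oracle_mw, numeric(1),
                                  USE.NAMES = FALSE), tolerance = 1e-9)
  expect_equal(prof$pi, isoelectric_point(rec$sequence))
  expect_equal(prof$frac_M[1], aa_composition("MSSTT")$frac_M)
  expect_true(all(prof$pi > 0 & prof$pi < 14))
  expect_true(all(prof$mw_da > aa_mass_table()$water_mass))
})
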