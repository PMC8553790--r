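# Build a small profile tibble directly, with controlled values.
fake_profiles <- function(pi, length = NULL, mw_da = NULL, host = "algae",
                          ids = NULL) {
  n <- NROW(pi)
  frac <- matrix(1 / 20, n, 20,
                 dimnames = list(NULL, paste0("frac_", .aa20)))
  dplyr::bind_cols(
    tibble::tibble(
      id = ids %||% paste0("p", seq_len(n)),
      host_group = rep_len(host, n),
      length = length %||% rep(100L, n),
      mw_da = mw_da %||% rep(11000, n),
      pi = pi,
      ambiguous_count = 0L
    ),
    tibble::as_tibble(frac)
  )
}

test_that("pI partition is disjoint, exhaustive, and honours the tolerance", {
  p <- partition_by_pi(fake_profiles(c(5, 7, 9)), neutral_tol = 0.005)
  expect_equal(as.character(p$pi_class), c("acidic", "neutral", "basic"))

  expect_equal(
    as.character(partition_by_pi(fake_profiles(6.996))$pi_class), "neutral")
  p0 <- partition_by_pi(fake_profiles(c(6.999999, 7, 7.000001)),
                        neutral_tol = 0)
  expect_equal(as.character(p0$pi_class), c("acidic", "neutral", "basic"))

  set.seed(71)
  for (tol in c(0, 0.005, 0.5)) {
    p <- partition_by_pi(fake_profiles(runif(200, 0, 14)), neutral_tol = tol)
    expect_true(all(!is.na(p$pi_class)))
    expect_equal(sum(table(p$pi_class)), 200)
  }
})

test_that("host summaries are unweighted per-protein means with first-in-order extremes", {
  prof <- fake_profiles(c(5, 9), length = c(10L, 20L), mw_da = c(10000, 30000))
  s <- summarize_hosts(prof)
  expect_equal(s$n_proteins, 2L)
  expect_equal(s$mean_length, 15)
  expect_equal(s$mean_mw_kda, 20)
  expect_equal(s$mean_pi, 7)
  expect_equal(s$pct_acidic, 50)
  expect_equal(s$pct_basic, 50)
  expect_equal(s$pct_neutral, 0)
  expect_equal(s$pct_acidic + s$pct_neutral + s$pct_basic, 100)
  expect_equal(sum(s[paste0("pct_", .aa20)]), 100, tolerance = 1e-9)
  expect_equal(s$longest_id, "p2")
  expect_equal(s$shortest_id, "p1")

  # single profile: summary echoes it, all extremes point to it
  s1 <- summarize_hosts(fake_profiles(6.2, length = 42L, mw_da = 5000))
  expect_equal(s1$mean_pi, 6.2)
  expect_equal(s1$longest_id, s1$shortest_id)
  expect_equal(s1$max_pi_id, s1$min_pi_id)

  # ties resolved by input order
  tie <- summarize_hosts(fake_profiles(c(6, 6), length = c(10L, 10L)))
  expect_equal(tie$longest_id, "p1")
})

test_that("summary means match an independent two-pass computation", {
  set.seed(72)
  prof <- fake_profiles(runif(500, 2, 12), length = sample(5:2000, 500, TRUE),
                        mw_da = runif(500, 600, 9e5))
  s <- summarize_hosts(prof)
  expect_equal(s$mean_length, sum(prof$length) / nrow(prof), tolerance = 1e-9)
  expect_equal(s$mean_pi, sum(prof$pi) / nrow(prof), tolerance = 1e-9)
  expect_equal(s$acidic_mean_pi, mean(prof$pi[prof$pi < 6.995]),
               tolerance = 1e-9)
})

test_that("kingdom pooling weights proteins, not hosts", {
  prof <- dplyr::bind_rows(
    fake_profiles(6, length = 10L, host = "algae", ids = "a1"),
    fake_profiles(rep(6, 3), length = rep(20L, 3), host = "fungi",
                  ids = paste0("f", 1:3))
  )
  k <- summarize_kingdom(prof)
  expect_equal(glance(k)$mean_length, 17.5)   # pooled, not mean-of-means (15)
  expect_equal(mean(tidy(k)$mean_length), 15)
  expect_equal(glance(k)$n_proteins, sum(tidy(k)$n_proteins))

  k1 <- summarize_kingdom(fake_profiles(c(5, 6), host = "algae"))
  expect_equal(glance(k1)$mean_pi, tidy(k1)$mean_pi)

  # unassigned records are excluded everywhere, keeping counts consistent
  k2 <- summarize_kingdom(dplyr::bind_rows(
    prof, fake_profiles(7, host = "unassigned", ids = "u1")))
  expect_equal(glance(k2)$n_proteins, 4L)
})

test_that("rank_hosts sorts ascending with alphabetical tie-break", {
  s <- dplyr::bind_rows(
    summarize_hosts(fake_profiles(c(5, 6), mw_da = c(22000, 22000), host = "bacteria")),
    summarize_hosts(fake_profiles(c(5, 6), mw_da = c(98000, 98000), host = "fungi")),
    summarize_hosts(fake_profiles(c(5, 6), mw_da = c(28000, 28000), host = "algae"))
  )
  r <- rank_hosts(s, key = "mean_mw")
  expect_equal(r$host_group, c("bacteria", "algae", "fungi"))
  expect_setequal(r$host_group, s$host_group)

  s_tie <- s
  s_tie$mean_mw_kda <- 10
  expect_equal(rank_hosts(s_tie, "mean_mw")$host_group,
               sort(s$host_group))
  expect_error(rank_hosts(s, key = "mean_banana"))
})

test_that("recovered means converge to generating means as n grows", {
  spec_for <- function(n) synthetic_spec(
    "conv", component_spec(1, log(150), 0.3), n_proteins = n, seed = 99)
  err <- vapply(c(50, 400), function(n) {
    prof <- physchem_profile(sample_proteome(spec_for(n)))
    abs(mean(prof$length) - exp(log(150) + 0.3^2 / 2))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("composition matrix rows are percentages summing to 100", {
  prof <- dplyr::bind_rows(
    fake_profiles(c(5, 6), host = "algae"),
    fake_profiles(c(7, 8), host = "fungi", ids = c("f1", "f2"))
  )
  m <- composition_matrix(summarize_kingdom(prof))
  expect_equal(dim(m), c(2L, 20L))
  expect_equal(unname(rowSums(m)), c(100, 100), tolerance = 1e-9)
})
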