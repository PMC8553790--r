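test_that("pearson handles the worked examples and rejects degenerate input", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1)
  # hand computation: sum(dx*dy) / sqrt(sum(dx^2) * sum(dy^2)) = 3/sqrt(84/9)
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 4)), 3 / sqrt(2 * 42 / 9),
               tolerance = 1e-12)
  expect_equal(round(pearson(c(1, 2, 3), c(1, 2, 4)), 3), 0.982)

  two_pass <- function(x, y) {
    dx <- x - mean(x); dy <- y - mean(y)
    sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  }
  set.seed(81)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(pearson(x, y), two_pass(x, y), tolerance = 1e-12)
    # affine invariance with positive scale
    expect_equal(pearson(2.5 * x + 3, y), pearson(x, y), tolerance = 1e-9)
  }
  expect_error(pearson(1:3, 1:4), class = "proteomap_validation_error")
  expect_error(pearson(1:2, 1:2), class = "proteomap_validation_error")
  expect_error(pearson(c(1, 1, 1), 1:3), class = "proteomap_validation_error")
})

test_that("correlation matrices are symmetric with unit diagonal", {
  set.seed(82)
  m <- matrix(runif(3 * 20, 2, 8), 3, 20,
              dimnames = list(c("algae", "bacteria", "fungi"), .aa20))
  m <- m / rowSums(m) * 100
  hc <- host_correlation(m)
  expect_identical(hc$r, t(hc$r))
  expect_equal(unname(diag(hc$r)), rep(1, 3))
  expect_true(all(hc$r >= -1 & hc$r <= 1))

  rc <- residue_correlation(m)
  expect_equal(dim(rc$r), c(20L, 20L))
  expect_identical(rc$r, t(rc$r))
  expect_equal(unname(diag(rc$r)), rep(1, 20))
})

test_that("identical host rows and duplicated or mirrored residue columns give |r| = 1", {
  set.seed(83)
  base <- runif(20, 1, 9)
  m <- rbind(algae = base, archaea = base, bacteria = runif(20, 1, 9))
  expect_equal(host_correlation(m)$r["algae", "archaea"], 1, tolerance = 1e-12)

  m2 <- matrix(runif(5 * 20), 5, 20, dimnames = list(NULL, .aa20))
  m2[, "R"] <- m2[, "A"]            # twin columns
  m2[, "N"] <- 10 - m2[, "A"]       # anti-correlated construction
  rc <- residue_correlation(m2)
  expect_equal(rc$r["A", "R"], 1, tolerance = 1e-12)
  expect_equal(rc$r["A", "N"], -1, tolerance = 1e-12)
})

test_that("host correlation decays as independent noise grows", {
  set.seed(84)
  shared <- runif(20, 2, 8)
  mean_offdiag <- vapply(c(0.05, 0.5, 2.5), function(noise) {
    m <- t(vapply(1:4, function(i) shared + rnorm(20, 0, noise), numeric(20)))
    rownames(m) <- c("algae", "archaea", "bacteria", "fungi")
    r <- host_correlation(m)$r
    mean(r[upper.tri(r)])
  }, numeric(1))
  expect_true(all(diff(mean_offdiag) < 0))
})

test_that("tidy.corr_matrix returns long format with Fisher-z intervals", {
  set.seed(85)
  m <- matrix(runif(3 * 20, 2, 8), 3, 20,
              dimnames = list(c("algae", "bacteria", "fungi"), .aa20))
  long <- tidy(host_correlation(m))
  expect_equal(nrow(long), 9L)
  expect_named(long, c("label1", "label2", "r", "conf.low", "conf.high"))
  off <- long[long$label1 != long$label2, ]
  expect_true(all(off$conf.low < off$r & off$r < off$conf.high))
})

test_that("NIPALS captures rank-1 structure and deflation shrinks the residual", {
  t_true <- seq(-5, 5, length.out = 12)
  x <- cbind(2 * t_true, -1 * t_true) + 10
  p <- pca_nipals(x, n_components = 1)
  expect_gte(p$explained_variance_fraction[1], 0.9999)

  set.seed(86)
  X <- matrix(rnorm(9 * 20), 9, 20)
  Xc <- sweep(X, 2, colMeans(X))
  resid_norm <- vapply(1:4, function(k) {
    fit <- pca_nipals(X, n_components = k)
    sqrt(sum((Xc - fit$scores %*% t(fit$loadings))^2))
  }, numeric(1))
  expect_true(all(diff(resid_norm) < 0))
})

test_that("NIPALS matches the spectral (eigendecomposition) oracle", {
  set.seed(87)
  for (rep in 1:3) {
    X <- matrix(rnorm(9 * 20), 9, 20)
    fit <- pca_nipals(X, n_components = 3, tol = 1e-12, max_iter = 500)
    Xc <- sweep(X, 2, colMeans(X))
    eig <- eigen(crossprod(Xc), symmetric = TRUE)
    evf_oracle <- eig$values[1:3] / sum(diag(crossprod(Xc)))
    expect_equal(fit$explained_variance_fraction, evf_oracle, tolerance = 1e-6)
    for (k in 1:3) {
      v <- eig$vectors[, k]
      expect_equal(abs(sum(fit$loadings[, k] * v)), 1, tolerance = 1e-6)
    }
  }
})

test_that("NIPALS loadings are orthonormal and variance fractions well-behaved", {
  set.seed(88)
  X <- matrix(rnorm(8 * 15), 8, 15)
  fit <- pca_nipals(X, n_components = 4, tol = 1e-12, max_iter = 500)
  g <- crossprod(fit$loadings)
  expect_equal(unname(diag(g)), rep(1, 4), tolerance = 1e-9)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-6)
  evf <- fit$explained_variance_fraction
  expect_true(all(diff(evf) <= 1e-9))
  expect_lte(sum(evf), 1 + 1e-9)
  # explained variance is invariant to row permutation
  fit2 <- pca_nipals(X[sample(nrow(X)), ], n_components = 4, tol = 1e-12,
                     max_iter = 500)
  expect_equal(fit2$explained_variance_fraction, evf, tolerance = 1e-9)
  expect_error(pca_nipals(X, n_components = 8),
               class = "proteomap_validation_error")
})
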