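# Correlation structure and NIPALS principal-component analysis of
# composition matrices.

#' Pearson product-moment correlation
#'
#' Thin, validated wrapper around [stats::cor()]: requires equal lengths of
#' at least 3 and non-constant vectors (a constant vector has no defined
#' correlation).
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return The correlation coefficient r.
#' @export
#' @examples
#' pearson(c(1, 2, 3), c(1, 2, 4))
pearson <- function(x, y) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length.", class = "proteomap_validation_error")
  }
  if (length(x) < 3L) {
    abort("Need at least 3 paired observations.", class = "proteomap_validation_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Correlation is undefined for a constant vector.",
          class = "proteomap_validation_error")
  }
  stats::cor(x, y, method = "pearson")
}

.new_corr_matrix <- function(r, n) {
  structure(list(r = r, method = "pearson", n = n), class = "corr_matrix")
}

.check_nonconstant_rows <- function(mat, margin, what) {
  sds <- apply(mat, margin, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("Correlation is undefined: constant ", what, ": ",
                 paste(dimnames(mat)[[margin]][sds == 0], collapse = ", ")),
          class = "proteomap_validation_error")
  }
}

#' Host-by-host correlation of composition
#'
#' Pairwise Pearson correlation between the 20-element composition rows of
#' each pair of host groups.
#'
#' @param matrix Host-by-residue composition matrix ([composition_matrix()]).
#' @return A `corr_matrix` object (hosts x hosts). `tidy()` yields a long
#'   tibble with Fisher-z confidence intervals; `autoplot()` a heat map.
#' @export
host_correlation <- function(matrix) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 3L)
  .check_nonconstant_rows(matrix, 1L, "host row(s)")
  .new_corr_matrix(stats::cor(t(matrix), method = "pearson"), n = ncol(matrix))
}

#' Residue-by-residue correlation of composition
#'
#' Pairwise Pearson correlation between the across-host abundance vectors of
#' each pair of residues.
#'
#' @inheritParams host_correlation
#' @return A `corr_matrix` object (20 x 20 residues).
#' @export
residue_correlation <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 3L)
  .check_nonconstant_rows(matrix, 2L, "residue column(s)")
  .new_corr_matrix(stats::cor(matrix, method = "pearson"), n = nrow(matrix))
}

#' @export
print.corr_matrix <- function(x, digits = 3, ...) {
  cat("Pearson correlation matrix (", nrow(x$r), " x ", ncol(x$r),
      "), n = ", x$n, " paired observations\n", sep = "")
  print(round(x$r, digits))
  invisible(x)
}

#' Tidy a correlation matrix
#'
#' @param x A `corr_matrix`.
#' @param conf_level Confidence level for the Fisher z-transform interval
#'   (requires n > 3 paired observations; otherwise `NA`).
#' @param ... Unused.
#' @return Long tibble: `label1`, `label2`, `r`, `conf.low`, `conf.high`.
#' @export
#' @exportS3Method generics::tidy
tidy.corr_matrix <- function(x, conf_level = 0.95, ...) {
  labs <- rownames(x$r)
  long <- tidyr::expand_grid(label1 = labs, label2 = labs)
  long$r <- as.vector(t(x$r))
  if (x$n > 3) {
    z <- atanh(pmin(pmax(long$r, -1 + 1e-15), 1 - 1e-15))
    se <- 1 / sqrt(x$n - 3)
    crit <- stats::qnorm(1 - (1 - conf_level) / 2)
    long$conf.low <- tanh(z - crit * se)
    long$conf.high <- tanh(z + crit * se)
  } else {
    long$conf.low <- NA_real_
    long$conf.high <- NA_real_
  }
  long
}

#' Principal-component analysis by NIPALS
#'
#' Sequential extraction of principal components by nonlinear iterative
#' partial least squares: for each component, power iteration alternates the
#' score and loading vectors until the score change falls below `tol`, then
#' the fitted rank-1 layer is deflated from the matrix. The input is
#' column-centered and left unscaled (the convention for compositional
#' percentage tables). Sign convention: the largest-magnitude loading of
#' each component is made positive.
#'
#' @param x Numeric matrix or data frame of numeric columns; rows are
#'   observations (rownames become score labels).
#' @param n_components Number of components; at most `min(nrow - 1, ncol)`.
#' @param max_iter Maximum power iterations per component (default 100).
#' @param tol Convergence tolerance on the relative score-vector change
#'   (default `1e-8`).
#' @return A `nipals_pca` object: `scores`, `loadings`,
#'   `explained_variance_fraction`, `n_iterations`, `converged`, `center`.
#'   `tidy()` extracts scores/loadings/variance tables, `glance()` a one-row
#'   summary, `autoplot()` a score plot.
#' @export
pca_nipals <- function(x, n_components = 2L, max_iter = 100L, tol = 1e-8) {
  x <- as.matrix(x)
  stopifnot(is.numeric(x), nrow(x) >= 2L, max_iter >= 1L, tol > 0)
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (n_components > kmax) {
    abort(paste0("n_components must be <= min(rows - 1, cols) = ", kmax),
          class = "proteomap_validation_error")
  }
  center <- colMeans(x)
  X <- sweep(x, 2L, center)
  total_ss <- sum(X^2)
  scores <- matrix(0, nrow(x), n_components,
                   dimnames = list(rownames(x), paste0("PC", seq_len(n_components))))
  loadings <- matrix(0, ncol(x), n_components,
                     dimnames = list(colnames(x), paste0("PC", seq_len(n_components))))
  evf <- numeric(n_components)
  iters <- integer(n_components)
  converged <- logical(n_components)
  for (k in seq_len(n_components)) {
    col_ss <- colSums(X^2)
    t_vec <- X[, which.max(col_ss)]
    if (max(col_ss) < .Machine$double.eps * total_ss) {
      warn(paste0("Residual matrix is numerically rank deficient; component ",
                  k, " and beyond are zero."))
      break
    }
    for (it in seq_len(max_iter)) {
      p <- crossprod(X, t_vec) / sum(t_vec^2)
      p <- p / sqrt(sum(p^2))
      t_new <- X %*% p
      delta <- sum((t_new - t_vec)^2) / max(sum(t_new^2), .Machine$double.eps)
      t_vec <- as.numeric(t_new)
      if (delta < tol) {
        converged[k] <- TRUE
        break
      }
    }
    iters[k] <- it
    j <- which.max(abs(p))
    if (p[j] < 0) {
      p <- -p
      t_vec <- -t_vec
    }
    scores[, k] <- t_vec
    loadings[, k] <- p
    evf[k] <- sum(t_vec^2) / total_ss
    X <- X - tcrossprod(t_vec, p)
  }
  structure(
    list(scores = scores, loadings = loadings,
         explained_variance_fraction = evf, n_iterations = iters,
         converged = converged, center = center, total_ss = total_ss),
    class = "nipals_pca"
  )
}

#' @export
print.nipals_pca <- function(x, ...) {
  k <- length(x$explained_variance_fraction)
  cat("NIPALS PCA:", k, "component(s)\n")
  cat("Explained variance fraction:",
      paste(sprintf("%.4f", x$explained_variance_fraction), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a NIPALS PCA
#'
#' @param x A `nipals_pca` object.
#' @param matrix Which table to return: `"scores"` (rows x components),
#'   `"loadings"` (variables x components) or `"variance"`.
#' @param ... Unused.
#' @return A long tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.nipals_pca <- function(x, matrix = c("scores", "loadings", "variance"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "variance") {
    return(tibble(
      component = seq_along(x$explained_variance_fraction),
      explained_variance_fraction = x$explained_variance_fraction,
      n_iterations = x$n_iterations,
      converged = x$converged
    ))
  }
  m <- x[[matrix]]
  out <- as_tibble(m)
  out$label <- rownames(m) %||% as.character(seq_len(nrow(m)))
  tidyr::pivot_longer(out, cols = -"label", names_to = "component",
                      values_to = if (matrix == "scores") "score" else "loading")
}

#' @export
#' @exportS3Method generics::glance
glance.nipals_pca <- function(x, ...) {
  tibble(
    n_components = length(x$explained_variance_fraction),
    cum_explained_variance = sum(x$explained_variance_fraction),
    all_converged = all(x$converged)
  )
}
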