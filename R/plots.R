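# ggplot2 renderings of the result objects. All figures derive from the
# same tables the TSV exports contain; plotting is never load-bearing.

#' Plot a virtual 2D proteome map
#'
#' @param object A `map2d` from [build_map()].
#' @param ... Unused.
#' @return A ggplot: pI on x, log10 molecular weight on y, tile fill by
#'   protein count (empty cells blank).
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.map2d <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$count > 0L, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pi_bin, y = .data$mw_bin,
                                  fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "proteins") +
    ggplot2::labs(x = "isoelectric point (pH)",
                  y = "molecular weight (log10 Da)",
                  title = "Virtual 2D proteome map") +
    ggplot2::theme_minimal()
}

#' Plot a modality classification
#'
#' @param object A `modality_result` from [classify_modality()].
#' @param data The profile tibble the result was computed from (needed to
#'   redraw the kernel density).
#' @param ... Unused.
#' @return A ggplot of the pI marginal density with detected modes marked.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.modality_result <- function(object, data, ...) {
  p <- object$parameters
  dens <- kde_1d(data$pi,
                 grid = seq(p$pi_range[1], p$pi_range[2], length.out = p$grid_n),
                 bandwidth_factor = p$bandwidth_factor)
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$mode_locations,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "isoelectric point (pH)", y = "density",
                  title = paste0("pI marginal: ", object$label)) +
    ggplot2::theme_minimal()
}

#' Correlation heat map
#'
#' @param object A `corr_matrix`.
#' @param ... Passed to [tidy.corr_matrix()].
#' @return A ggplot heat map of pairwise Pearson r.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.corr_matrix <- function(object, ...) {
  d <- tidy(object, ...)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label1, y = .data$label2,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "navy", midpoint = 0,
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Pearson correlation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' PCA score plot
#'
#' @param object A `nipals_pca`.
#' @param components Two component indices to display (default `c(1, 2)`).
#' @param ... Unused.
#' @return A ggplot of labelled scores.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.nipals_pca <- function(object, components = c(1, 2), ...) {
  stopifnot(length(components) == 2L,
            max(components) <= ncol(object$scores))
  evf <- object$explained_variance_fraction
  d <- tibble(
    label = rownames(object$scores) %||% as.character(seq_len(nrow(object$scores))),
    x = object$scores[, components[1]],
    y = object$scores[, components[2]]
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  label = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", components[1], 100 * evf[components[1]]),
      y = sprintf("PC%d (%.1f%%)", components[2], 100 * evf[components[2]]),
      title = "NIPALS PCA scores"
    ) +
    ggplot2::theme_minimal()
}
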