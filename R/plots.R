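#' Plot a GP-ratio permutation null
#'
#' Observed GP-ratio histogram (bars) with the permutation-null mean
#' (line) and its 95% percentile band (ribbon), per bin.
#'
#' @param object A `gp_shuffle_null`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gp_shuffle_null <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_center)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed),
                      fill = "grey70", width = 1 / object$n_bins) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$null_ci_lower,
                                      ymax = .data$null_ci_upper),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_mean)) +
    ggplot2::labs(
      x = sprintf("GP ratio (GPi / (GPe + GPi), %s)", object$weight),
      y = "MSNs per bin",
      title = "Observed pallidal selectivity vs permutation null") +
    ggplot2::theme_minimal()
}

#' Heatmap of a cell-type connectivity matrix
#'
#' @param object A `type_matrix`.
#' @param weight `"area"` or `"count"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.type_matrix <- function(object, weight = c("area", "count"),
                                 ...) {
  weight <- match.arg(weight)
  d <- tidy(object)
  d$value <- d[[weight]]
  d$pre_type <- factor(d$pre_type, levels = rev(object$types))
  d$post_type <- factor(d$post_type, levels = object$types)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$post_type, y = .data$pre_type,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "postsynaptic type", y = "presynaptic type",
                  fill = weight,
                  title = sprintf("Connectivity matrix (%s normalization)",
                                  object$normalization)) +
    ggplot2::theme_minimal()
}

#' Scatter of an embedding
#'
#' Plots the first one or two principal components of a
#' [zscore_embed()] result, coloured by cell type when available.
#'
#' @param object A `morpho_embedding`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.morpho_embedding <- function(object, ...) {
  has2 <- "PC2" %in% names(object)
  p <- if (has2) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$PC1, y = 0))
  }
  if ("type" %in% names(object)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$type),
                                 alpha = 0.7)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7)
  }
  p + ggplot2::labs(title = "Morphometric embedding") +
    ggplot2::theme_minimal()
}
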