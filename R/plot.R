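#' Plot ancestry principal components
#'
#' Scatterplot of two principal components, optionally coloured by a sample
#' grouping (case/control, population label, ...).
#'
#' @param object an `rv_pca` from [compute_pca()].
#' @param samples optional sample tibble joined by `sample_id`; when given,
#'   points are coloured by `colour_by`.
#' @param pcs integer vector of length 2: which components to plot.
#' @param colour_by column of `samples` used for colour.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rv_pca <- function(object, samples = NULL, pcs = c(1, 2),
                            colour_by = "group", ...) {
  d <- object$scores
  xvar <- paste0("PC", pcs[1])
  yvar <- paste0("PC", pcs[2])
  if (!is.null(samples)) {
    d <- dplyr::left_join(d, samples, by = "sample_id")
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(.data[[xvar]], .data[[yvar]]))
  if (!is.null(samples) && colour_by %in% names(d)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour_by]]),
                                 alpha = 0.7, size = 1)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7, size = 1)
  }
  p + ggplot2::labs(
    x = sprintf("%s (%.1f%%)", xvar, 100 * object$explained_variance[pcs[1]]),
    y = sprintf("%s (%.1f%%)", yvar, 100 * object$explained_variance[pcs[2]])
  ) + ggplot2::theme_minimal()
}

#' Plot per-sample homozygosity rates
#'
#' Histogram of the proportion of the mapped autosomal genome in runs of
#' homozygosity, with the consanguinity threshold marked.
#'
#' @param object an `rv_roh` from [homozygosity_rate()].
#' @param threshold consanguinity threshold drawn as a vertical line.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rv_roh <- function(object, threshold = 0.01, ...) {
  ggplot2::ggplot(object$rates,
                  ggplot2::aes(.data$homozygosity_rate)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey35") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "fraction of autosomal genome in ROH",
                  y = "samples") +
    ggplot2::theme_minimal()
}

#' Forest plot of burden-test odds ratios
#'
#' One row per variant set (and gene subset when present) with the Firth
#' odds ratio and its 95% profile-likelihood confidence interval on a log
#' scale.
#'
#' @param burden tibble of `burden_test()` rows (e.g. `report$burden`).
#' @return a ggplot object.
#' @export
plot_burden <- function(burden) {
  d <- burden
  d$label <- if ("gene_subset" %in% names(d)) {
    paste(d$gene_subset, d$variant_set_label, sep = " / ")
  } else {
    d$variant_set_label
  }
  d <- d[!is.na(d$odds_ratio), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$odds_ratio, y = .data$label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI, log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the pairwise kinship distribution
#'
#' Histogram of KING-robust kinship estimates with the degree thresholds
#' (0.0442, 0.0884, 0.177, 0.354) marked.
#'
#' @param kinship tibble from [king_kinship()].
#' @return a ggplot object.
#' @export
plot_kinship <- function(kinship) {
  thresholds <- c(0.0442, 0.0884, 0.177, 0.354)
  ggplot2::ggplot(kinship[!is.na(kinship$phi), ],
                  ggplot2::aes(.data$phi)) +
    ggplot2::geom_histogram(bins = 80, fill = "grey35") +
    ggplot2::geom_vline(xintercept = thresholds, linetype = "dotted",
                        colour = "firebrick") +
    ggplot2::labs(x = expression(hat(phi)), y = "pairs") +
    ggplot2::theme_minimal()
}
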