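# Diagnostic figures for the main result types.

#' Plot RONA per climate variable and stand set
#'
#' @param rona RONA tibble from [rona_per_stand()] / [run_pipeline()].
#' @return A ggplot object (boxplots of per-stand RONA by variable, filled by
#'   stand set, facetted by method when several are present).
#' @export
plot_rona <- function(rona) {
  p <- ggplot2::ggplot(rona, ggplot2::aes(x = .data$variable, y = .data$rona,
                                          fill = .data$stand_set)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "Risk of non-adaptedness",
                  fill = "Stand set") +
    ggplot2::theme_minimal()
  if ("method" %in% names(rona) && length(unique(rona$method)) > 1) {
    p <- p + ggplot2::facet_wrap(~method)
  }
  p
}

#' Plot significant-association counts per variable
#'
#' @param counts Count table from [count_associations()].
#' @return A ggplot object.
#' @export
plot_association_counts <- function(counts) {
  p <- ggplot2::ggplot(counts, ggplot2::aes(x = .data$variable, y = .data$n))
  if ("stand_set" %in% names(counts)) {
    p <- p + ggplot2::aes(fill = .data$stand_set) +
      ggplot2::geom_col(position = "dodge")
  } else {
    p <- p + ggplot2::geom_col()
  }
  if ("method" %in% names(counts)) p <- p + ggplot2::facet_wrap(~method)
  p + ggplot2::labs(x = NULL, y = "Significant SNP associations",
                    fill = "Stand set") +
    ggplot2::theme_minimal()
}

#' Plot the population-structure PCA
#'
#' @param pca Result of [pca_structure()].
#' @param stands Optional stand table supplying `stand_type` colours.
#' @return A ggplot object of PC1 vs PC2.
#' @export
plot_pca <- function(pca, stands = NULL) {
  sc <- pca$scores
  if (!is.null(stands)) {
    sc <- dplyr::left_join(sc, stands[, c("stand_id", "stand_type")],
                           by = "stand_id")
  }
  pv <- 100 * pca$prop_variance
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(stands)) p <- p + ggplot2::aes(colour = .data$stand_type)
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pv[1]),
                  y = sprintf("PC2 (%.1f%%)", pv[2]), colour = "Stand type") +
    ggplot2::theme_minimal()
}

#' Plot outgroup f3 by comparison class
#'
#' @param f3 Table from [f3_locality_scan()].
#' @return A ggplot object (boxplots of f3 by comparison class).
#' @export
plot_f3 <- function(f3) {
  ggplot2::ggplot(f3, ggplot2::aes(x = .data$class, y = .data$f3,
                                   fill = .data$class)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = expression(f[3])) +
    ggplot2::theme_minimal()
}
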