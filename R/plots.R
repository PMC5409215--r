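#' Plot an LD decay curve
#'
#' Binned mean r2 against distance with the (0, 1) anchor, the threshold
#' line, and the interpolated decay distance marked when defined.
#'
#' @param object a `slaf_decay` from [ld_decay()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.slaf_decay <- function(object, ...) {
  df <- rbind(tibble(center = 0, mean_r2 = 1, n_pairs = NA_integer_),
              object$bins)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$center / 1000, .data$mean_r2)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
  if (!is.na(object$decay_distance)) {
    p <- p + ggplot2::geom_vline(xintercept = object$decay_distance / 1000,
                                 linetype = 3)
  }
  p
}

#' Plot a cross-validation curve for the choice of K
#'
#' @param object a `slaf_cv` from [choose_k()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.slaf_cv <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$k, .data$cv_error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = tidy(object)[tidy(object)$k == best_k(object), ],
                        colour = "red", size = 2) +
    ggplot2::scale_x_continuous(breaks = object$k) +
    ggplot2::labs(x = "K", y = "cross-validation error") +
    ggplot2::theme_minimal()
}

#' Stacked ancestry bar plot
#'
#' Accessions ordered by their dominant genetic component within each
#' majority group, the conventional admixture display.
#'
#' @param object a `slaf_admixture` from [admixture_em()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.slaf_admixture <- function(object, ...) {
  q <- object$q
  major <- max.col(q)
  ord <- order(major, -q[cbind(seq_len(nrow(q)), major)])
  df <- tidy(object)
  df$accession <- factor(df$accession, levels = rownames(q)[ord])
  ggplot2::ggplot(df, ggplot2::aes(.data$accession, .data$ancestry,
                                   fill = .data$group)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "ancestry") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' PCA score plot
#'
#' @param object a `slaf_pca` from [pca_genotypes()].
#' @param ... unused.
#' @return a ggplot of the first two components coloured by ecotype.
#' @export
autoplot.slaf_pca <- function(object, ...) {
  ve <- object$variance_explained
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2, colour = .data$ecotype)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = sprintf("PC1 (%.2f%%)", 100 * ve[1]),
                  y = sprintf("PC2 (%.2f%%)", 100 * ve[2])) +
    ggplot2::theme_minimal()
}

#' Windowed SNP density along chromosomes
#'
#' @param wc window tibble from [windowed_snp_counts()].
#' @return a ggplot, one facet per chromosome.
#' @export
plot_snp_density <- function(wc) {
  ggplot2::ggplot(wc, ggplot2::aes((.data$start + .data$end) / 2e6,
                                   .data$n_snps)) +
    ggplot2::geom_col(width = diff(range(wc$end)) / 1e6 / nrow(wc),
                      fill = "grey30") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "SNPs per window") +
    ggplot2::theme_minimal()
}
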