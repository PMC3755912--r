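category_palette <- function(scheme) {
  if (scheme == "quantile") {
    c(small = "#33A02C", normal = "#555555", large = "#6A3D9A")
  } else {
    c(small = "#E6C200", normal = "#BBBBBB", large = "#1F78B4")
  }
}

#' Scatter plot of birth size against a phenotype
#'
#' One point per strain, coloured by birth-size category, with per-category
#' and overall Spearman rho annotated; the overall coefficient sits at the
#' bottom right. Colour semantics follow the categorisation scheme
#' (small/large in yellow/blue for the wild-type-SD scheme, green/purple
#' for the quantile scheme) and can be overridden.
#'
#' @inheritParams per_category_association
#' @param palette Named colour vector for `small`, `normal`, `large`
#'   (default depends on `scheme`).
#' @return A ggplot object.
#' @export
plot_birth_vs_phenotype <- function(params, assignments, phenotypes,
                                    phenotype = c("mean_size", "fitness",
                                                  "pct_g1"),
                                    cutoff = 0.20, scheme = "wt_sd",
                                    palette = NULL) {
  phenotype <- match.arg(phenotype)
  ycol <- switch(phenotype, mean_size = "mean_size",
                 fitness = "fitness_rank", pct_g1 = "pct_g1")
  ylab <- switch(phenotype, mean_size = "mean size (fl)",
                 fitness = "fitness rank (1 = most fit)",
                 pct_g1 = "%G1 DNA content")
  palette <- palette %||% category_palette(scheme)
  tab <- category_table(params, assignments, phenotypes, scheme)
  tab <- tab[!is.na(tab[[ycol]]), ]
  xcol <- xb_column(cutoff)
  assoc <- per_category_association(params, assignments, phenotypes,
                                    phenotype, cutoff, scheme)
  lab <- function(cat) {
    r <- assoc$rho[assoc$category == cat]
    if (is.na(r)) sprintf("%s: rho n/a", cat) else
      sprintf("%s: rho = %.2f", cat, r)
  }
  tab$label <- factor(tab$label, c("small", "normal", "large"))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data[[xcol]], y = .data[[ycol]],
                                    colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.4) +
    ggplot2::scale_colour_manual(values = palette, name = "birth size",
                                 drop = FALSE) +
    ggplot2::annotate("text", x = Inf, y = -Inf, hjust = 1.05, vjust = -0.5,
                      label = lab("overall")) +
    ggplot2::labs(
      x = sprintf("birth size x_b (fl, %g%% cutoff)", 100 * cutoff),
      y = ylab,
      subtitle = paste(lab("small"), lab("large"), sep = "   ")) +
    ggplot2::theme_classic()
}

#' Category boxplots of a phenotype
#'
#' One box per birth-size category: the box spans the quartiles, the band
#' inside the box is drawn at the group mean (the convention used for the
#' %G1 comparison figures; the median is available from
#' [boxplot_summary()]), whiskers reach the most extreme data within 1.5
#' IQR of the quartiles, and points beyond the whiskers are drawn as
#' filled circles.
#'
#' @inheritParams per_category_association
#' @param palette Named colour vector for `small`, `normal`, `large`.
#' @return A ggplot object.
#' @export
plot_category_box <- function(params, assignments, phenotypes,
                              phenotype = c("mean_size", "fitness",
                                            "pct_g1"),
                              cutoff = 0.20, scheme = "wt_sd",
                              palette = NULL) {
  phenotype <- match.arg(phenotype)
  ycol <- switch(phenotype, mean_size = "mean_size",
                 fitness = "fitness_rank", pct_g1 = "pct_g1")
  ylab <- switch(phenotype, mean_size = "mean size (fl)",
                 fitness = "fitness rank (1 = most fit)",
                 pct_g1 = "%G1 DNA content")
  palette <- palette %||% category_palette(scheme)
  gc <- group_mean_comparison(params, assignments, phenotypes, phenotype,
                              cutoff, scheme)
  g <- gc$groups[gc$groups$category != "overall", ]
  g$category <- factor(g$category, c("small", "normal", "large"))
  tab <- category_table(params, assignments, phenotypes, scheme)
  tab <- tab[!is.na(tab[[ycol]]), ]
  tab$category <- factor(tab$label, c("small", "normal", "large"))
  lims <- stats::setNames(g$whisker_lo, as.character(g$category))
  hims <- stats::setNames(g$whisker_hi, as.character(g$category))
  out <- tab[tab[[ycol]] < lims[as.character(tab$category)] |
               tab[[ycol]] > hims[as.character(tab$category)], ]
  ggplot2::ggplot(g, ggplot2::aes(x = .data$category)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$whisker_lo,
                                        ymax = .data$whisker_hi),
                           width = 0.25) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$mean, ymin = .data$q1,
                                        ymax = .data$q3,
                                        fill = .data$category),
                           width = 0.6) +
    ggplot2::geom_point(data = out,
                        ggplot2::aes(x = .data$category, y = .data[[ycol]]),
                        shape = 16, size = 1.3) +
    ggplot2::scale_fill_manual(values = palette, guide = "none") +
    ggplot2::labs(x = sprintf("birth size category (%s scheme)", scheme),
                  y = ylab) +
    ggplot2::theme_classic()
}
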