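#' Plot per-subject asymmetry scores by group
#'
#' Boxplots of the asymmetry score for each metric, split by group -- the
#' usual way lateralization comparisons are displayed. Positive scores mean
#' leftward dominance.
#'
#' @param asymmetry Tibble from [lateralize_cohort()].
#' @param cohort Cohort table with `subject_id` and `group`.
#' @param metrics Optional character vector restricting which metrics are
#'   shown.
#' @return A ggplot object.
#' @export
plot_lateralization <- function(asymmetry, cohort, metrics = NULL) {
  d <- dplyr::left_join(asymmetry[asymmetry$defined, ],
                        cohort[, c("subject_id", "group")],
                        by = "subject_id")
  if (!is.null(metrics)) d <- d[d$metric %in% metrics, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$as,
                                  fill = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.7, alpha = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "asymmetry score (+ = leftward)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot adjusted group differences in asymmetry
#'
#' Point-and-interval display of the covariate-adjusted group effect on each
#' metric's asymmetry score, with approximate 95% confidence intervals and
#' FDR-significant outcomes highlighted.
#'
#' @param object A `hemilat_comparison` from [compare_lateralization()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hemilat_comparison <- function(object, ...) {
  d <- as_tibble(unclass(object))
  d$lo <- d$effect - 1.96 * d$se
  d$hi <- d$effect + 1.96 * d$se
  ggplot2::ggplot(d, ggplot2::aes(x = .data$effect, y = .data$metric,
                                  colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::facet_grid(family ~ ., scales = "free_y", space = "free_y") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "adjusted group difference in asymmetry score",
                  y = NULL, colour = "FDR < 0.05") +
    ggplot2::theme_minimal()
}
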