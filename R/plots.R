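#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an accuracy table as single-cutoff ROC points
#'
#' Each test contributes one point at (1 - specificity, sensitivity) with
#' Clopper-Pearson error bars on the sensitivity, faceted by stratum; the
#' chance diagonal is drawn for reference.
#'
#' @param object A `snap_accuracy` table (see [accuracy_table()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.snap_accuracy <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$spec, y = .data$sens,
                                   colour = .data$test)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$sens_lo,
                                        ymax = .data$sens_hi), width = 0.02) +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity", colour = "test") +
    ggplot2::theme_minimal()
}

#' Plot normative amplitude ranges by group and age group
#'
#' Median with interquartile bars per group across age-group strata,
#' faceted by measure.
#'
#' @param ranges A range table (see [range_table()]).
#' @return A ggplot object.
#' @export
plot_range_table <- function(ranges) {
  df <- ranges[ranges$age_group != "whole", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_group, y = .data$median,
                                   colour = .data$group, group = .data$group)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "age group", y = "amplitude (µV) / ratio",
                  colour = "group") +
    ggplot2::theme_minimal()
}
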