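# ggplot2 visualizations for the main result types.

#' Plot pericentromeric repression curves
#'
#' LOH and heterozygous loess fits over fractional centromere distance,
#' with the repression window shaded.
#'
#' @param object A `repression_curves` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.repression_curves <- function(object, ...) {
  long <- object$curves %>%
    tidyr::pivot_longer(c("fit_loh", "fit_het"),
                        names_to = "group", values_to = "fit") %>%
    mutate(group = if_else(.data$group == "fit_loh", "LOH chromosomes",
                           "heterozygous chromosomes"))
  ggplot2::ggplot(long, ggplot2::aes(.data$frac_dist, .data$fit,
                                     colour = .data$group)) +
    ggplot2::annotate("rect", xmin = object$window[1],
                      xmax = object$window[2], ymin = -Inf, ymax = Inf,
                      alpha = 0.15) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      "LOH chromosomes" = "#c0392b", "heterozygous chromosomes" = "#2980b9"
    )) +
    ggplot2::labs(
      x = "fractional distance to centromere (0 = boundary, 1 = arm end)",
      y = if (object$value == "percentile") "arm-level expression percentile"
          else "expression z-score",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of a pooled odds-ratio meta-analysis
#'
#' @param object A `meta_or` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.meta_or <- function(object, ...) {
  per <- tidy(object) %>%
    mutate(
      conf_low = exp(.data$log_or - 1.96 * .data$std_error),
      conf_high = exp(.data$log_or + 1.96 * .data$std_error)
    )
  pooled <- glance(object) %>% mutate(study_id = "pooled (MH)")
  ggplot2::ggplot(per, ggplot2::aes(.data$estimate, .data$study_id)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::geom_pointrange(
      data = pooled,
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      colour = "#c0392b", shape = 18, linewidth = 1
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cohort motif
#'
#' Per-chromosome modal zygosity and copy states with their frequencies.
#'
#' @param motif Output of [cohort_motif()].
#' @return A ggplot.
#' @export
plot_cohort_motif <- function(motif) {
  long <- motif %>%
    select("chrom", "modal_zygosity", "zygosity_freq",
           "modal_copy", "copy_freq") %>%
    tidyr::pivot_longer(
      cols = c("zygosity_freq", "copy_freq"),
      names_to = "layer", values_to = "freq"
    ) %>%
    mutate(
      state = if_else(.data$layer == "zygosity_freq",
                      .data$modal_zygosity, .data$modal_copy),
      layer = if_else(.data$layer == "zygosity_freq", "zygosity",
                      "copy state")
    )
  ggplot2::ggplot(long, ggplot2::aes(
    factor(.data$chrom, levels = chrom_levels()), .data$freq,
    fill = .data$state
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~layer, ncol = 1) +
    ggplot2::labs(x = NULL, y = "modal state frequency", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot timing calls as cancer chromosome fractions
#'
#' @param timing_calls Output of [select_copy_model()].
#' @param cutoff Early/late cutoff drawn as a dashed line.
#' @return A ggplot.
#' @export
plot_timing <- function(timing_calls, cutoff = 0.85) {
  ok <- timing_calls %>% filter(.data$status == "ok")
  ggplot2::ggplot(ok, ggplot2::aes(.data$sample_id, .data$tumor_af,
                                   colour = .data$is_mad,
                                   shape = .data$is_mad)) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_jitter(width = 0.1, height = 0, size = 2) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#c0392b", `FALSE` = "grey55"),
      labels = c(`TRUE` = "MAD gene", `FALSE` = "other")
    ) +
    ggplot2::scale_shape_manual(
      values = c(`TRUE` = 18, `FALSE` = 16),
      labels = c(`TRUE` = "MAD gene", `FALSE` = "other")
    ) +
    ggplot2::labs(x = NULL, y = "cancer chromosome fraction (m/n)",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
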