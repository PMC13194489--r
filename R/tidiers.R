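#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a superposition into a per-residue tibble
#'
#' @param x A `superposition` from [kabsch_superpose()].
#' @param thresholds Deviation cuts for [deviation_bins()].
#' @param ... Unused.
#' @return Tibble: `residue`, `deviation`, `bin`.
#' @export
tidy.superposition <- function(x, thresholds = c(0.5, 2), ...) {
  tibble(residue = seq_len(x$n_aligned),
         deviation = x$per_residue_dev,
         bin = deviation_bins(x$per_residue_dev, thresholds))
}

#' @rdname tidy.superposition
#' @export
glance.superposition <- function(x, ...) {
  tibble(n_aligned = x$n_aligned, global_rmsd = x$global_rmsd,
         tm_score = x$tm_score)
}

#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(term = c("k", "y0"), estimate = c(x$k, x$y0))
}

#' @export
glance.growth_fit <- function(x, ...) {
  tibble(k = x$k, r_squared = x$r_squared,
         window_start = x$window[1], window_end = x$window[2],
         n = x$n, time_unit = x$time_unit)
}

#' @export
tidy.ss_comparison <- function(x, ...) {
  x$transitions
}

#' @export
glance.ss_comparison <- function(x, ...) {
  tibble(n_positions = x$n_positions, n_diff = x$n_diff,
         fraction_diff = x$fraction_diff, percent_diff = x$percent_diff,
         mean_strand_len_a = x$mean_strand_len_a,
         mean_strand_len_b = x$mean_strand_len_b,
         helix_content_a = x$helix_content_a,
         helix_content_b = x$helix_content_b)
}

#' @export
tidy.comparison_summary <- function(x, ...) {
  as_tibble(x) %>%
    tidyr::pivot_longer(-dplyr::any_of(c("comparison", "background_denominator")),
                        names_to = "statistic", values_to = "value",
                        values_transform = as.numeric)
}

#' @export
glance.evolved_lineage <- function(x, ...) {
  x$truth$counts
}

#' Per-residue deviation plot for a superposition
#'
#' @param object A `superposition`.
#' @param thresholds Deviation cuts for the colour bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.superposition <- function(object, thresholds = c(0.5, 2), ...) {
  d <- tidy(object, thresholds = thresholds)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$residue, y = .data$deviation,
                                  colour = .data$bin)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = thresholds, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_colour_manual(
      values = c(blue = "#2166ac", white = "grey60", red = "#b2182b")) +
    ggplot2::labs(x = "Residue", y = "Deviation (\u00c5)",
                  colour = "Similarity",
                  title = sprintf("RMSD %.2f \u00c5, TM-score %.2f",
                                  object$global_rmsd, object$tm_score)) +
    ggplot2::theme_minimal()
}

#' Fold-change bar plot for an expression result
#'
#' @param object An `expression_result` from [delta_delta_ct()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.expression_result <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data$fold,
                                  fill = .data$strain)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = 2^(.data$log2_fold - .data$sd_log2),
                   ymax = 2^(.data$log2_fold + .data$sd_log2)),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = NULL, y = "Fold change (2^-\u0394\u0394Ct)") +
    ggplot2::theme_minimal()
}

#' Growth-curve plot with the fitted exponential window
#'
#' @param object A `growth_fit`.
#' @param curve The curve tibble the fit came from.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.growth_fit <- function(object, curve, ...) {
  cv <- as_tibble(curve)
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::annotate("rect", xmin = object$window[1], xmax = object$window[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "steelblue") +
    ggplot2::geom_function(
      fun = function(t) object$y0 * exp(object$k * t),
      colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = sprintf("Time (%s)",
                              ifelse(is.na(object$time_unit), "units",
                                     object$time_unit)),
                  y = "Value (log scale)",
                  title = sprintf("k = %.3g, R\u00b2 = %.3f",
                                  object$k, object$r_squared)) +
    ggplot2::theme_minimal()
}
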