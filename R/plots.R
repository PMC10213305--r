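#' Scatter plot of SNP effects with fitted MR slopes
#'
#' Exposure effects against outcome effects, one point per SNP with +/- 1
#' SE error bars, overlaid with the fitted line of each method in
#' `results` (IVW and WME through the origin, MR-Egger with its intercept).
#'
#' @param set An `mr_harmonized` table.
#' @param results Tibble from [mr_all()]; intercepts are drawn at zero
#'   except for the MR-Egger row, whose intercept is refitted internally.
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(set, results = mr_all(set, seed = 1)) {
  set <- orient_positive_exposure(as_harmonized(set))
  lines <- tibble::tibble(method = results$method, slope = results$beta,
                          intercept = 0)
  if ("MR-Egger" %in% results$method && nrow(set) >= 3) {
    lines$intercept[lines$method == "MR-Egger"] <-
      mr_egger(set)$extra$intercept$estimate
  }
  ggplot2::ggplot(set, ggplot2::aes(x = .data$beta_x, y = .data$beta_y)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_y - .data$se_y,
                                        ymax = .data$beta_y + .data$se_y),
                           width = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta_x - .data$se_x,
                                         xmax = .data$beta_x + .data$se_x),
                            height = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept,
                                      colour = .data$method)) +
    ggplot2::labs(x = paste("SNP effect on",
                            attr(set, "exposure_label") %||% "exposure"),
                  y = paste("SNP effect on",
                            attr(set, "outcome_label") %||% "outcome"),
                  colour = "Method") +
    ggplot2::theme_minimal()
}

#' @describeIn funnel_data Funnel plot (ratio vs precision) with the pooled
#'   reference line.
#' @param object An `mr_funnel` table.
#' @param ... Unused.
#' @method autoplot mr_funnel
#' @export
autoplot.mr_funnel <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ratio,
                                       y = .data$precision)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "reference"),
                        linetype = "dashed") +
    ggplot2::labs(x = "Wald ratio (log odds)", y = "Precision (1/SE)") +
    ggplot2::theme_minimal()
}

#' @describeIn forest_data Forest plot of per-SNP and pooled odds ratios.
#' @param object An `mr_forest` table.
#' @param ... Unused.
#' @method autoplot mr_forest
#' @export
autoplot.mr_forest <- function(object, ...) {
  object$label <- factor(object$label, levels = rev(object$label))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$or, y = .data$label,
                                       colour = .data$kind)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' @describeIn leave_one_out Leave-one-out forest plot of the re-estimated
#'   odds ratios.
#' @param object An `mr_loo` table.
#' @param ... Unused.
#' @method autoplot mr_loo
#' @export
autoplot.mr_loo <- function(object, ...) {
  object$omitted <- factor(object$omitted, levels = rev(object$omitted))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$or, y = .data$omitted)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$influential)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "IVW odds ratio with SNP omitted", y = "Omitted SNP") +
    ggplot2::theme_minimal()
}
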