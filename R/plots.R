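#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_errorbar
#'   geom_hline geom_tile geom_text labs scale_x_log10 facet_wrap
#'   scale_fill_gradient2 theme_minimal
NULL

#' Plot a logistic concentration–response fit
#'
#' Data points (jittered replicate blocks as given) with the pooled fitted
#' curve on a log10 concentration axis.
#'
#' @param object A [fit_logistic()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot logistic_fit
#' @export
autoplot.logistic_fit <- function(object, ...) {
  d <- dplyr::filter(object$data, .data$conc_M > 0)
  p <- object$pooled
  grid <- tibble(conc_M = 10^seq(log10(min(d$conc_M)), log10(max(d$conc_M)),
                                 length.out = 100))
  grid$response <- logistic_response(grid$conc_M, p$basal, p$e_max,
                                     p$log_ec50, p$hill)
  ggplot(d, aes(x = .data$conc_M, y = .data$response)) +
    geom_point(alpha = 0.6) +
    geom_line(data = grid, colour = "#2166ac") +
    scale_x_log10() +
    labs(x = "[agonist] (M)", y = "response",
         title = sprintf("%d-parameter logistic fit", object$n_params)) +
    theme_minimal()
}

#' Plot an operational-model fit
#'
#' Per-ligand data points and fitted operational curves.
#'
#' @param object A [fit_operational()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot operational_fit
#' @export
autoplot.operational_fit <- function(object, ...) {
  d <- dplyr::filter(object$data, .data$conc_M > 0)
  sh <- object$shared
  grid <- tidyr::expand_grid(
    object$estimates[, c("ligand", "log_tau", "log_KA")],
    conc_M = 10^seq(log10(min(d$conc_M)), log10(max(d$conc_M)),
                    length.out = 100)
  )
  grid$response <- operational_response(grid$conc_M, sh$Em, grid$log_tau,
                                        grid$log_KA, sh$n_hill, sh$basal)
  ggplot(d, aes(x = .data$conc_M, y = .data$response,
                colour = .data$ligand)) +
    geom_point(alpha = 0.6) +
    geom_line(data = grid) +
    scale_x_log10() +
    labs(x = "[agonist] (M)", y = "response", colour = "ligand",
         title = "Operational-model fit (shared system parameters)") +
    theme_minimal()
}

#' Forest-style plot of bias estimates
#'
#' Mean delta-delta-log(tau/K_A) per ligand with 95% confidence intervals;
#' the dashed line at zero separates bias toward the reference pathway
#' (positive) from bias away from it.
#'
#' @param object A [bias_interval()] / [bias_analysis()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bias_result
#' @export
autoplot.bias_result <- function(object, ...) {
  d <- as_tibble(object)
  ggplot(d, aes(x = .data$delta_delta, y = .data$ligand)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    geom_point() +
    ggplot2::geom_errorbarh(aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
                            height = 0.15) +
    (if ("pathway_pair" %in% names(d)) facet_wrap(~pathway_pair) else NULL) +
    labs(x = expression(Delta * Delta * log(tau / K[A])), y = NULL) +
    theme_minimal()
}

#' Cross-receptor log2 fold-change heatmap
#'
#' Tile heatmap of [receptor_response_heatmap()] output; below-range entries
#' are marked with an "X" instead of a colour value.
#'
#' @param heat Tibble from [receptor_response_heatmap()].
#' @return A ggplot object.
#' @export
plot_receptor_heatmap <- function(heat) {
  ggplot(heat, aes(x = .data$readout, y = .data$receptor,
                   fill = .data$log2_fc)) +
    geom_tile(colour = "grey80") +
    geom_text(data = dplyr::filter(heat, .data$below_range),
              aes(x = .data$readout, y = .data$receptor, label = "X"),
              inherit.aes = FALSE) +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         na.value = "grey95") +
    labs(x = NULL, y = NULL, fill = expression(log[2] ~ "fold change")) +
    theme_minimal()
}
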