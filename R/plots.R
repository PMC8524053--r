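#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a threshold scan
#'
#' Shows the Poisson-fit p-value along the St grid with the acceptance
#' level and the selected threshold marked; the transition from rejection
#' (GOE-like spacings) to acceptance locates St.
#'
#' @param object A `threshold_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot threshold_scan
#' @export
autoplot.threshold_scan <- function(object, ...) {
  scan <- object$scan
  ggplot2::ggplot(scan[scan$feasible, ], ggplot2::aes(x = .data$st, y = .data$p_poisson)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$st, colour = "red") +
    ggplot2::labs(
      x = "candidate similarity threshold St",
      y = "Poisson NNSD goodness-of-fit p",
      title = sprintf("RMT threshold scan (selected St = %.2f)", object$st)
    ) +
    ggplot2::theme_minimal()
}

#' Zi-Pi role plot
#'
#' The classic keystone plot: within-module connectivity Zi against
#' among-module connectivity Pi, with the role-threshold lines and points
#' coloured by domain.
#'
#' @param roles Classified roles from [classify_roles()].
#' @param zi_threshold,pi_threshold Threshold lines (defaults 2.5, 0.62).
#' @return A ggplot.
#' @export
plot_zi_pi <- function(roles, zi_threshold = 2.5, pi_threshold = 0.62) {
  ggplot2::ggplot(roles, ggplot2::aes(
    x = .data$pi, y = .data$zi,
    colour = .data$domain, shape = .data$role
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = zi_threshold, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = pi_threshold, linetype = "dashed") +
    ggplot2::labs(
      x = "among-module connectivity (Pi)",
      y = "within-module connectivity (Zi)"
    ) +
    ggplot2::theme_minimal()
}

#' Degree-distribution plot with power-law fit
#'
#' Degree-frequency histogram on log-log axes with the least-squares line
#' whose R-squared is reported by [network_summary()].
#'
#' @param net A `co_network`.
#' @return A ggplot.
#' @export
plot_degree_distribution <- function(net) {
  deg <- igraph::degree(net$graph)
  tab <- table(deg[deg > 0])
  df <- tibble::tibble(k = as.numeric(names(tab)), freq = as.numeric(tab))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$freq)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "degree k", y = "frequency",
      title = sprintf("degree distribution (power-law R² = %.3f)", powerlaw_r2(deg))
    ) +
    ggplot2::theme_minimal()
}

#' Panel TPM heatmap
#'
#' Gene-by-compartment tile plot of log10 TPM for a panel profile, with
#' undetected genes marked by a cross (the display convention for absent
#' panel members).
#'
#' @param profile Long profile from [panel_profile()].
#' @return A ggplot.
#' @export
plot_panel_heatmap <- function(profile) {
  profile <- dplyr::mutate(profile, log_tpm = log10(.data$tpm + 1))
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$compartment, y = .data$gene)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$log_tpm), colour = "white") +
    ggplot2::geom_point(
      data = dplyr::filter(profile, !.data$detected),
      shape = 4, size = 3, colour = "grey30"
    ) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = "log10(TPM+1)") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y", space = "free_y") +
    ggplot2::theme_minimal()
}
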