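#' Plot a simulated trajectory
#'
#' One line per component on a log10 concentration axis, with a dashed marker
#' at the perturbation/step time when the trajectory carries one.
#'
#' @param object A `cu_trajectory` from [integrate_system()] (or the
#'   `trajectory` element of a perturbation/step result).
#' @param components Components to show. Default all ten.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cu_trajectory <- function(object, components = component_names(), ...) {
  long <- tidyr::pivot_longer(object, cols = dplyr::all_of(components),
                              names_to = "component", values_to = "concentration")
  long$component <- factor(long$component, levels = components)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time,
                                          y = .data$concentration,
                                          colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (min)", y = "concentration (uM)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  t_event <- attr(object, "t_event")
  if (!is.null(t_event)) {
    p <- p + ggplot2::geom_vline(xintercept = t_event, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' @rdname autoplot.cu_trajectory
#' @export
plot_trajectory <- function(object, components = component_names(), ...) {
  autoplot.cu_trajectory(object, components = components, ...)
}

#' Plot a nutrient-copper sweep
#'
#' Steady-state concentrations against nutrient COPPER, faceted by component,
#' both axes log10. The flatness of the CU facet across the regulated window
#' is the homeostatic signature.
#'
#' @param object A `cu_sweep` from [sweep_nutrient()].
#' @param components Components to show. Default all ten.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cu_sweep <- function(object, components = component_names(), ...) {
  long <- tidyr::pivot_longer(object, cols = dplyr::all_of(components),
                              names_to = "component", values_to = "concentration")
  long$component <- factor(long$component, levels = components)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$copper,
                                     y = .data$concentration)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "nutrient COPPER (uM)", y = "steady-state concentration (uM)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cu_sweep
#' @export
plot_sweep <- function(object, components = component_names(), ...) {
  autoplot.cu_sweep(object, components = components, ...)
}

#' Plot titration points against a Hill curve
#'
#' @param points Tibble with columns `ligand`, `apo_fraction`.
#' @param fit A [hill_fit()] drawn as the reference curve.
#' @return A ggplot object.
#' @export
plot_titration <- function(points, fit) {
  span <- range(points$ligand)
  curve <- tibble::tibble(
    ligand = exp(seq(log(span[1]), log(span[2]), length.out = 200))
  )
  curve$apo_fraction <- hill_apo_fraction(curve$ligand, fit)
  ggplot2::ggplot(points, ggplot2::aes(x = .data$ligand,
                                       y = .data$apo_fraction)) +
    ggplot2::geom_line(data = curve, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "labile copper (uM)", y = "apo fraction") +
    ggplot2::theme_minimal()
}

#' Plot per-condition apparent rate constants
#'
#' Apparent rate constants across the ordered titration conditions, faceted by
#' reaction with free y scales; invariant reactions read as flat lines,
#' regulated ones as rising curves.
#'
#' @param k_table Long tibble from [apparent_rate_constants()].
#' @param reactions Reactions to show. Default all present.
#' @param condition_order Condition ordering on the x axis.
#' @return A ggplot object.
#' @export
plot_apparent_constants <- function(k_table, reactions = NULL,
                                    condition_order = c("MBCS", "M0", "M10",
                                                        "M50", "M100", "M175",
                                                        "M250")) {
  d <- if (is.null(reactions)) k_table else {
    dplyr::filter(k_table, .data$reaction %in% reactions)
  }
  d$condition <- factor(d$condition, levels = condition_order)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$k_apparent,
                                  group = .data$reaction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~reaction, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "apparent rate constant (uM/min)") +
    ggplot2::theme_minimal()
}
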