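#' Plot a compartment or size trajectory
#'
#' @param data A trajectory tibble (`time` plus state columns).
#' @return A ggplot object with one line per state component.
#' @export
plot_trajectory <- function(data) {
  long <- tidyr::pivot_longer(data, -"time", names_to = "component",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "density / size", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot marginal_density
#' @export
autoplot.marginal_density <- function(object, ...) {
  s <- density_summary(object)
  ggplot2::ggplot(object, ggplot2::aes(.data$value, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = s$mle, linetype = "dotted",
                        colour = "red") +
    ggplot2::labs(x = attr(object, "parameter"), y = "density") +
    ggplot2::theme_minimal()
}

#' Loss-potential scatter of visited parameter estimates
#'
#' Scatter of the pooled training samples in two parameter coordinates,
#' coloured by the negative log loss, so the minima of the loss potential
#' stand out as bright clusters.
#'
#' @param fit A [calibrate()] result.
#' @param x,y Parameter names (defaults: the first two).
#' @return A ggplot object.
#' @export
plot_loss_potential <- function(fit, x = NULL, y = NULL) {
  pars <- fit$net_cfg$param_names
  x <- x %||% pars[1L]
  y <- y %||% pars[2L]
  df <- dplyr::filter(fit$samples, is.finite(.data$loss))
  ggplot2::ggplot(df, ggplot2::aes(.data[[x]], .data[[y]],
                                   colour = -log(.data$loss + 1e-300))) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::scale_colour_viridis_c(name = "-log J") +
    ggplot2::theme_minimal()
}

#' Per-initialisation loss traces
#'
#' @param fit A [calibrate()] result.
#' @return A ggplot object: loss against optimizer step, one line per
#'   initialisation, log-scaled.
#' @export
plot_loss_trace <- function(fit) {
  df <- dplyr::mutate(
    dplyr::group_by(fit$samples, .data$init_id),
    step = dplyr::row_number()
  )
  ggplot2::ggplot(dplyr::filter(df, is.finite(.data$loss)),
                  ggplot2::aes(.data$step, .data$loss,
                               group = .data$init_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "optimizer step", y = "loss J") +
    ggplot2::theme_minimal()
}

#' Plot an ensemble prediction with error bands
#'
#' @param ensemble A [predict_ensemble()] result.
#' @return A ggplot object: ensemble mean with one-SD ribbons.
#' @export
plot_ensemble <- function(ensemble) {
  ggplot2::ggplot(ensemble,
                  ggplot2::aes(.data$time, .data$mean,
                               colour = .data$component,
                               fill = .data$component)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "prediction", colour = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}
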