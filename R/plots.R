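fucci_colours <- function() {
  c(red = "#D7263D", yellow = "#E6B800", green = "#1B998B")
}

#' Plot the agent configuration of a simulation state
#'
#' @param state A `sim_state`.
#' @param point_size Point size passed to [ggplot2::geom_point()].
#' @return A ggplot object.
#' @export
plot_state <- function(state, point_size = 1.2) {
  stopifnot(inherits(state, "sim_state"))
  pos <- state_positions(state)
  ggplot2::ggplot(pos, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$phase)) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::scale_colour_manual(values = fucci_colours()) +
    ggplot2::coord_fixed(xlim = c(0, state$geom$width),
                         ylim = c(0, state$geom$height)) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("t = %.1f h, %d cells",
                                  state$time, nrow(pos))) +
    ggplot2::theme_minimal()
}

#' Plot tracked-cell trajectories
#'
#' @param trajectories Trajectory tibble from [simulate_invasion()].
#' @return A ggplot object (one panel per tracked cell).
#' @export
plot_trajectories <- function(trajectories) {
  trajectories <- tibble::as_tibble(trajectories)
  ggplot2::ggplot(trajectories,
                  ggplot2::aes(x = .data$x_um, y = .data$y_um,
                               group = .data$cell_id)) +
    ggplot2::geom_path(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$phase), size = 0.9) +
    ggplot2::scale_colour_manual(values = fucci_colours()) +
    ggplot2::facet_wrap(~cell_id, scales = "free") +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Marginal posterior distributions of an SMC-ABC fit
#'
#' Density panels of the six marginal posteriors, optionally after
#' regression adjustment and with the generating/true values marked.
#'
#' @param object An `smc_abc_fit`.
#' @param adjusted Plot the regression-adjusted sample.
#' @param truth Optional named numeric of true parameter values (dashed
#'   lines).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.smc_abc_fit <- function(object, adjusted = FALSE, truth = NULL,
                                 ...) {
  draws <- if (adjusted) regression_adjust(object)
           else object$particles[object$prior$param]
  lvls <- unique(c(intersect(param_names(), names(draws)), names(draws)))
  long <- tidyr::pivot_longer(draws, dplyr::everything(),
                              names_to = "param", values_to = "value")
  long$param <- factor(long$param, levels = lvls)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::facet_wrap(~param, scales = "free") +
    ggplot2::labs(x = "rate (h⁻¹)", y = "posterior density") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    tr <- tibble::tibble(param = factor(names(truth), levels = lvls),
                         value = as.numeric(truth))
    p <- p + ggplot2::geom_vline(data = tr,
                                 ggplot2::aes(xintercept = .data$value),
                                 linetype = "dashed")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Posterior predictive check plot
#'
#' Histograms of the simulated summary statistics from
#' [posterior_predictive()] with the observed values as dashed lines.
#'
#' @param predictive Tibble from [posterior_predictive()].
#' @param observed Observed `summary_vector`.
#' @return A ggplot object.
#' @export
plot_posterior_predictive <- function(predictive, observed) {
  stats <- names(unclass(observed))
  long <- tidyr::pivot_longer(predictive[stats], dplyr::everything(),
                              names_to = "statistic", values_to = "value")
  long$statistic <- factor(long$statistic, levels = stats)
  obs <- tibble::tibble(statistic = factor(stats, levels = stats),
                        value = as.numeric(unclass(observed)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 25, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(data = obs, ggplot2::aes(xintercept = .data$value),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(x = "summary statistic", y = "simulations") +
    ggplot2::theme_minimal()
}
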