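#' Plot a simulated trajectory
#'
#' Firing rate of every unit against time, with the synaptic and depression
#' variables optionally faceted underneath.
#'
#' @param object A `rate_trajectory` from [simulate_network()].
#' @param variables Which state variables to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rate_trajectory <- function(object, variables = c("r", "s", "d"),
                                     ...) {
  variables <- match.arg(variables, c("r", "s", "d"), several.ok = TRUE)
  long <- tidyr::pivot_longer(object, cols = dplyr::all_of(variables),
                              names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = factor(.data$unit))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (units of the rate time constant)", y = NULL,
                  colour = "unit") +
    ggplot2::theme_minimal()
}

#' Plot a basin-of-attraction map
#'
#' Grid cells in the (r1, r2) plane colored by the attractor reached, with
#' the stable fixed points (dots) and saddles (crosses) overlaid.
#'
#' @param object A `basin_map` from [map_basins()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.basin_map <- function(object, ...) {
  catalog <- attr(object, "catalog")
  fp <- tibble(
    r1 = vapply(catalog$r, `[`, numeric(1), 1),
    r2 = vapply(catalog$r, `[`, numeric(1), 2),
    stable = catalog$stable
  )
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r1, y = .data$r2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$pattern)) +
    ggplot2::geom_point(data = dplyr::filter(fp, .data$stable),
                        shape = 16, size = 2) +
    ggplot2::geom_point(data = dplyr::filter(fp, !.data$stable),
                        shape = 4, size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "initial rate r1", y = "initial rate r2",
                  fill = "final state") +
    ggplot2::theme_minimal()
}

#' Plot a stimulus-response map
#'
#' For single-pulse maps, cells are colored by the final binary pattern; for
#' two-pulse maps, by the number of binarized switches (the 2-switch cells
#' are the maximally history-dependent regime).
#'
#' @param object A `response_map` from [single_pulse_map()] or
#'   [double_pulse_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.response_map <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$tau_dur,
                                            y = .data$I_app))
  p <- if ("n_switches" %in% names(object)) {
    p + ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$n_switches))) +
      ggplot2::labs(fill = "switches")
  } else {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$final_pattern)) +
      ggplot2::labs(fill = "final state")
  }
  p + ggplot2::labs(x = "pulse duration", y = "pulse amplitude") +
    ggplot2::theme_minimal()
}

#' Plot sequence-length statistics across an ensemble
#'
#' Per-network mean and maximum numbers of distinct states visited under the
#' repeated-stimulus protocol.
#'
#' @param object A `sequence_stats` tibble from [sequence_stats()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sequence_stats <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              cols = c("ell_mean", "ell_max"),
                              names_to = "measure", values_to = "length")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$network, y = .data$length,
                                     colour = .data$measure)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "network", y = "distinct states visited") +
    ggplot2::theme_minimal()
}
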