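#' Plot phase time series
#'
#' One line per oscillator, phases in `[0, 2*pi)`; synchrony groups appear as
#' bundles of overlapping lines.
#'
#' @param object A `kuramoto_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kuramoto_trajectory <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$theta,
                                   group = .data$oscillator_id,
                                   colour = factor(.data$oscillator_id))) +
    ggplot2::geom_line(linewidth = 0.3, show.legend = FALSE) +
    ggplot2::labs(x = "time", y = expression(Theta),
                  title = paste0("Phase trajectories (K = ",
                                 object$config$K, ")")) +
    ggplot2::theme_minimal()
}

#' Unit-circle snapshot of the oscillators
#'
#' @param traj A `kuramoto_trajectory`.
#' @param time Time of the snapshot (defaults to the final time).
#' @return A ggplot object.
#' @export
plot_phase_circle <- function(traj, time = max(traj$times)) {
  theta <- phases_at(traj, time)
  df <- tibble::tibble(oscillator_id = as.integer(names(theta)),
                       x = cos(theta), y = sin(theta))
  circle <- tibble::tibble(a = seq(0, 2 * pi, length.out = 200))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(data = circle,
                       ggplot2::aes(cos(.data$a), sin(.data$a)),
                       colour = "grey70", inherit.aes = FALSE) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0("t = ", time), x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot order parameter against coupling strength
#'
#' Mean final-time order parameter with a one-standard-deviation ribbon
#' across replicates.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(.data$K, .data$order_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(0, .data$order_mean - .data$order_sd),
      ymax = pmin(1, .data$order_mean + .data$order_sd)),
      alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "coupling coefficient K", y = "order parameter |z|") +
    ggplot2::theme_minimal()
}

#' Synchrony-group onset diagram
#'
#' Horizontal segments spanning each persistent group's members at the
#' coupling value where that composition first appears.
#'
#' @param result A `sweep_result`.
#' @return A ggplot object.
#' @export
plot_onset <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  onset <- result$onset
  if (nrow(onset) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_minimal() +
             ggplot2::labs(title = "no persistent groups on this grid"))
  }
  segs <- dplyr::bind_rows(lapply(seq_len(nrow(onset)), function(i) {
    ids <- as.integer(strsplit(onset$members[i], ",")[[1]])
    tibble::tibble(first_K = onset$first_K[i],
                   xmin = min(ids), xmax = max(ids))
  }))
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$xmin, xend = .data$xmax,
                                       y = .data$first_K,
                                       yend = .data$first_K),
                          linewidth = 2, alpha = 0.6) +
    ggplot2::labs(x = "oscillator id", y = "onset coupling K") +
    ggplot2::theme_minimal()
}
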