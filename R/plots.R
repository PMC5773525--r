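# ggplot2 views of runs and sweeps.

type_cols <- c(a_plus = "#d66a6a", b_plus = "#8c1a1a",
               a_minus = "#7aa6d6", b_minus = "#1a3f8c")

counts_long <- function(traj, time_col) {
  tidyr::pivot_longer(traj,
                      cols = c("a_plus", "b_plus", "a_minus", "b_minus"),
                      names_to = "type", values_to = "count") |>
    dplyr::rename(time = dplyr::all_of(time_col))
}

#' @rdname pcd_autoplot
#' @export
autoplot.pcd_competition <- function(object, ...) {
  traj <- tidy(object)
  ggplot2::ggplot(counts_long(traj, "round"),
                  ggplot2::aes(.data$time, .data$count,
                               colour = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = type_cols) +
    ggplot2::labs(x = "round", y = "count",
                  title = paste("well-mixed competition -", object$winner))
}

#' Plot methods for simulation runs
#'
#' `autoplot()` draws the four type counts over time; lattice and ABM runs
#' add the mean assortment trajectory on a second panel-like scale.
#'
#' @name pcd_autoplot
#' @param object A run object.
#' @param ... Unused.
#' @return A ggplot.
NULL

#' @rdname pcd_autoplot
#' @export
autoplot.lattice_competition <- function(object, ...) {
  traj <- tidy(object)
  n_sites <- with(object$params, rows * cols)
  ggplot2::ggplot(counts_long(traj, "round"),
                  ggplot2::aes(.data$time, .data$count,
                               colour = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = traj,
                       ggplot2::aes(.data$round, .data$mean_r * n_sites),
                       colour = "black", linetype = 2,
                       inherit.aes = FALSE) +
    ggplot2::scale_colour_manual(values = type_cols) +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~ . / n_sites, name = "mean r")) +
    ggplot2::labs(x = "round", y = "count",
                  title = paste("lattice competition -", object$winner))
}

#' @rdname pcd_autoplot
#' @export
autoplot.abm_run <- function(object, ...) {
  traj <- tidy(object)
  cap <- prod(object$final_world$dims) * object$final_world$capacity
  ggplot2::ggplot(counts_long(traj, "step"),
                  ggplot2::aes(.data$time, .data$count,
                               colour = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = traj,
                       ggplot2::aes(.data$step, .data$assortment * cap),
                       colour = "purple", linetype = 2,
                       inherit.aes = FALSE) +
    ggplot2::scale_colour_manual(values = type_cols) +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~ . / cap, name = "assortment r")) +
    ggplot2::labs(x = "step", y = "count",
                  title = paste("agent-based run -", object$winner))
}

#' Tile plot of a win-fraction sweep
#'
#' @param sweep A sweep tibble (from [win_fraction_sweep()] or
#'   [competition_sweep()]).
#' @param x,y Names of the two parameter columns to map to the axes.
#' @return A ggplot.
#' @examples
#' sw <- win_fraction_sweep(switch_prob = c(0.05, 0.2), pcd_prob = 0.05,
#'                          assortment = c(0.5, 0.9), disaster_prob = 0.1,
#'                          reps = 2, capacity = 200, max_rounds = 100,
#'                          seed = 1)
#' plot_win_surface(sw, "switch_prob", "assortment")
#' @export
plot_win_surface <- function(sweep, x, y) {
  ggplot2::ggplot(sweep,
                  ggplot2::aes(factor(.data[[x]]), factor(.data[[y]]),
                               fill = .data$win_fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "#1a3f8c",
                                  mid = "white", high = "#8c1a1a",
                                  limits = c(0, 1)) +
    ggplot2::labs(x = x, y = y, fill = "PCD+ win\nfraction")
}
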