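# broom-style tidiers for the three run objects.

#' @rdname pcd_tidiers
#' @param x A `pcd_competition`, `lattice_competition` or `abm_run` object.
#' @param ... Unused.
#' @export
tidy.pcd_competition <- function(x, ...) {
  if (is.null(x$trajectory)) {
    stop("competition was run with `record_trajectory = FALSE`",
         call. = FALSE)
  }
  x$trajectory
}

#' @rdname pcd_tidiers
#' @export
glance.pcd_competition <- function(x, ...) {
  fs <- x$final_state
  tibble::tibble(
    winner = x$winner, rounds = x$rounds,
    a_plus = fs[["a_plus"]], b_plus = fs[["b_plus"]],
    a_minus = fs[["a_minus"]], b_minus = fs[["b_minus"]],
    plus_fraction = (fs[["a_plus"]] + fs[["b_plus"]]) / max(sum(fs), 1))
}

#' Tidiers for simulation runs
#'
#' `tidy()` returns the per-round (or per-step) trajectory as a tibble;
#' `glance()` returns a one-row summary.  For `abm_run` objects `glance()`
#' also reports the grand mean log population size and the coefficient of
#' variation of population size over the recorded trajectory, the two
#' monoculture demography summaries of the agent-based model.
#'
#' @name pcd_tidiers
#' @return A tibble.
#' @examples
#' cmp <- run_competition(capacity = 200, max_rounds = 100, seed = 1)
#' tidy(cmp)
#' glance(cmp)
NULL

#' @rdname pcd_tidiers
#' @export
tidy.lattice_competition <- function(x, ...) x$trajectory

#' @rdname pcd_tidiers
#' @export
glance.lattice_competition <- function(x, ...) {
  last <- x$trajectory[nrow(x$trajectory), ]
  late <- dplyr::filter(x$trajectory,
                        .data$round > max(.data$round) / 2)
  tibble::tibble(
    winner = x$winner, rounds = x$rounds,
    a_plus = last$a_plus, b_plus = last$b_plus,
    a_minus = last$a_minus, b_minus = last$b_minus,
    mean_r_final = last$mean_r,
    mean_r_late = mean(late$mean_r, na.rm = TRUE),
    n_disasters = sum(x$trajectory$disaster))
}

#' @rdname pcd_tidiers
#' @export
tidy.abm_run <- function(x, ...) x$trajectory

#' @rdname pcd_tidiers
#' @export
glance.abm_run <- function(x, ...) {
  tot <- x$trajectory$total
  tot <- tot[tot > 0]
  tibble::tibble(
    winner = x$winner, steps = x$steps,
    mean_log_pop = mean(log(tot)),
    cv_pop = stats::sd(x$trajectory$total) / mean(x$trajectory$total),
    mean_assortment = mean(x$trajectory$assortment, na.rm = TRUE),
    mean_diversity_plus = mean(x$trajectory$diversity_plus, na.rm = TRUE),
    mean_diversity_minus = mean(x$trajectory$diversity_minus,
                                na.rm = TRUE))
}
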