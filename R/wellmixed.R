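# Spatially-implicit stochastic competitions with a fixed assortment
# probability.  The single-round operations wrap the same compiled
# primitives the full competition loop uses.

#' Stochastic PCD/replacement round
#'
#' The stochastic counterpart of [deterministic_round()]: each PCD+ cell
#' dies independently with probability `pcd_prob`; each dying cell is, with
#' probability `assortment`, replaced by an own-genotype offspring of the
#' same phenotype that switches with probability `p_plus`, and otherwise by
#' a PCD- offspring whose phenotype is drawn from the competitor's phenotype
#' frequencies at the start of the round and then switched with probability
#' `p_minus`.  Total population is unchanged.  If the competitor is extinct
#' the replacement returns to the PCD+ genotype (see
#' [deterministic_round()]).
#'
#' @param state Four non-negative integer counts (`a_plus`, `b_plus`,
#'   `a_minus`, `b_minus`).
#' @param pcd_prob Per-round PCD probability of the PCD+ strain.
#' @param assortment Fixed assortment probability `r`.
#' @param p_plus,p_minus Switch probabilities of the PCD+ and PCD-
#'   genotypes (`p_minus` defaults to `p_plus`).
#' @param seed Optional integer seed applied just for this draw.
#' @return A `population_state`.
#' @examples
#' st <- population_state(50, 50, 50, 50)
#' pcd_regrowth_round(st, pcd_prob = 0.1, assortment = 0.6, p_plus = 0.05,
#'                    seed = 1)
#' @export
pcd_regrowth_round <- function(state, pcd_prob, assortment, p_plus,
                               p_minus = p_plus, seed = NULL) {
  x <- as_int_state(state)
  if (sum(x) == 0) stop("empty population", call. = FALSE)
  check_prob(pcd_prob, "pcd_prob")
  check_prob(assortment, "assortment")
  check_prob(p_plus, "p_plus")
  check_prob(p_minus, "p_minus")
  out <- run_seeded(seed,
    wm_pcd_round_cpp(x, pcd_prob, assortment, p_plus, p_minus))
  state_out(out)
}

#' Apply a disaster to a population state
#'
#' Reduces the targeted phenotype of both genotypes: exact annihilation when
#' `kill_fraction = 1`, otherwise binomial survivors with survival
#' probability `1 - kill_fraction`.
#'
#' @inheritParams pcd_regrowth_round
#' @param target `"A"` or `"B"`, the phenotype hit.
#' @param kill_fraction Fraction of the targeted phenotype killed.
#' @return A `population_state`.
#' @examples
#' apply_disaster(population_state(30, 20, 40, 10), "A")
#' @export
apply_disaster <- function(state, target, kill_fraction = 1, seed = NULL) {
  x <- as_int_state(state)
  target <- match.arg(target, c("A", "B"))
  check_prob(kill_fraction, "kill_fraction")
  out <- run_seeded(seed,
    wm_disaster_cpp(x, if (target == "A") 0L else 1L, kill_fraction))
  state_out(out)
}

#' Regrow a population to carrying capacity
#'
#' Sequential births: each birth's parent is drawn uniformly from the
#' current, growing population; the offspring inherits the parent's
#' genotype and phenotype and switches phenotype with that genotype's
#' switch probability.
#'
#' @inheritParams pcd_regrowth_round
#' @param capacity Carrying capacity `N` to restore.
#' @return A `population_state` with total `capacity`.
#' @examples
#' regrow_to_capacity(population_state(10, 0, 0, 0), p_plus = 0.01,
#'                    capacity = 100, seed = 1)
#' @export
regrow_to_capacity <- function(state, p_plus, p_minus = p_plus, capacity,
                               seed = NULL) {
  x <- as_int_state(state)
  if (sum(x) == 0) {
    stop("cannot regrow an extinct population (both genotypes dead)",
         call. = FALSE)
  }
  check_count(capacity, "capacity", min = 1)
  if (sum(x) > capacity) {
    stop("population already exceeds `capacity`", call. = FALSE)
  }
  check_prob(p_plus, "p_plus")
  check_prob(p_minus, "p_minus")
  out <- run_seeded(seed, wm_regrow_cpp(x, p_plus, p_minus,
                                        as.integer(capacity)))
  state_out(out)
}

#' Run one well-mixed competition
#'
#' Discrete rounds until one genotype goes extinct or `max_rounds` is
#' reached.  Each round: with probability `disaster_prob` a disaster strikes
#' a uniformly chosen phenotype (both genotypes); the survivors regrow to
#' carrying capacity; then one stochastic PCD/replacement round executes.
#' At the round cap the winner is the genotype holding the majority
#' (a tie is its own outcome class).
#'
#' @param p_plus,p_minus Switch probabilities of the two genotypes.
#' @param pcd_prob PCD probability of the PCD+ strain.
#' @param assortment Fixed assortment probability `r`.
#' @param disaster_prob Per-round disaster probability `d`.
#' @param capacity Carrying capacity `N`.
#' @param kill_fraction Disaster kill fraction (1 = annihilation).
#' @param max_rounds Round cap.
#' @param init Initial `population_state`; defaults to `capacity / 4` of
#'   each of the four types.
#' @param record_trajectory Keep the per-round trajectory (set `FALSE` in
#'   large sweeps).
#' @param seed Optional integer seed.
#' @return An object of class `"pcd_competition"`: a list with `winner`
#'   (one of `"PCD+"`, `"PCD-"`, `"both_extinct"`,
#'   `"timeout_majority_PCD+"`, `"timeout_majority_PCD-"`,
#'   `"timeout_tie"`), `rounds`, `final_state`, `trajectory` (a tibble, or
#'   `NULL`) and `params`.  Use [tidy()] / [glance()] / [autoplot()].
#' @examples
#' cmp <- run_competition(p_plus = 0.1, pcd_prob = 0.05, assortment = 0.9,
#'                        disaster_prob = 0.1, capacity = 400,
#'                        max_rounds = 500, seed = 1)
#' glance(cmp)
#' @export
run_competition <- function(p_plus = 0.1, p_minus = p_plus, pcd_prob = 0.05,
                            assortment = 0.5, disaster_prob = 0.1,
                            capacity = 10000, kill_fraction = 1,
                            max_rounds = 10000, init = NULL,
                            record_trajectory = TRUE, seed = NULL) {
  check_prob(p_plus, "p_plus"); check_prob(p_minus, "p_minus")
  check_prob(pcd_prob, "pcd_prob"); check_prob(assortment, "assortment")
  check_prob(disaster_prob, "disaster_prob")
  check_prob(kill_fraction, "kill_fraction")
  check_count(capacity, "capacity", min = 4)
  check_count(max_rounds, "max_rounds", min = 1)
  if (is.null(init)) {
    q <- floor(capacity / 4)
    init <- population_state(q, q, q, q)
  }
  x <- as_int_state(init)
  if (sum(x) > capacity) {
    stop("initial population exceeds `capacity`", call. = FALSE)
  }
  res <- run_seeded(seed, wm_run_competition_cpp(
    x, p_plus, p_minus, pcd_prob, assortment, disaster_prob, kill_fraction,
    as.integer(capacity), as.integer(max_rounds), record_trajectory))
  traj <- NULL
  if (record_trajectory) {
    tr <- res$trajectory
    traj <- tibble::tibble(
      round = tr$round, a_plus = tr$a_plus, b_plus = tr$b_plus,
      a_minus = tr$a_minus, b_minus = tr$b_minus,
      disaster = tr$disaster == 1L,
      target = decode_target(tr$target))
  }
  structure(list(
    winner = decode_winner(res$winner),
    rounds = res$rounds,
    final_state = state_out(res$state),
    trajectory = traj,
    params = list(p_plus = p_plus, p_minus = p_minus, pcd_prob = pcd_prob,
                  assortment = assortment, disaster_prob = disaster_prob,
                  capacity = capacity, kill_fraction = kill_fraction,
                  max_rounds = max_rounds),
    seed = seed), class = "pcd_competition")
}

#' @export
print.pcd_competition <- function(x, ...) {
  cat("<pcd_competition>  winner:", x$winner, " rounds:", x$rounds, "\n")
  print(x$final_state)
  invisible(x)
}

#' Sweep PCD+ win fractions over a parameter grid
#'
#' Runs `reps` independent competitions for every combination of the
#' supplied parameter vectors and tallies the outcome classes.  The win
#' fraction counts extinction wins and timeout-majority wins for PCD+,
#' divided by the competitions in which at least one genotype survived and
#' the cap did not end in an exact tie; a cell where no competition
#' qualifies gets `NaN`, not 0.
#'
#' @inheritParams run_competition
#' @param switch_prob Switch probability vector (applied to both genotypes).
#' @param reps Replicates per parameter combination.
#' @param seed Root seed; replicate streams are derived from it.
#' @return A tibble with one row per combination: outcome-class counts,
#'   `win_fraction` and its binomial standard error.
#' @examples
#' win_fraction_sweep(switch_prob = 0.1, pcd_prob = 0.05,
#'                    assortment = c(0.5, 0.9), disaster_prob = 0.1,
#'                    reps = 4, capacity = 200, max_rounds = 200, seed = 1)
#' @export
win_fraction_sweep <- function(switch_prob, pcd_prob, assortment,
                               disaster_prob, reps = 100, capacity = 10000,
                               kill_fraction = 1, max_rounds = 10000,
                               seed = NULL) {
  check_count(reps, "reps", min = 1)
  grid <- tidyr::crossing(switch_prob = switch_prob, pcd_prob = pcd_prob,
                          assortment = assortment,
                          disaster_prob = disaster_prob)
  q <- floor(capacity / 4)
  init <- as.integer(c(q, q, q, q))
  rows <- purrr::imap(purrr::transpose(as.list(grid)), function(g, idx) {
    winners <- integer(reps)
    for (i in seq_len(reps)) {
      res <- run_seeded(
        if (is.null(seed)) NULL else child_seed(seed, idx, i),
        wm_run_competition_cpp(init, g$switch_prob, g$switch_prob,
                               g$pcd_prob, g$assortment, g$disaster_prob,
                               kill_fraction, as.integer(capacity),
                               as.integer(max_rounds), FALSE))
      winners[i] <- res$winner
    }
    summarise_winners(winners, reps)
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(rows))
}

summarise_winners <- function(winners, reps) {
  wins_plus <- sum(winners == 1L)
  wins_minus <- sum(winners == 2L)
  timeout_plus <- sum(winners == 4L)
  timeout_minus <- sum(winners == 5L)
  ties <- sum(winners == 6L)
  both_extinct <- sum(winners == 3L)
  n_valid <- reps - both_extinct - ties
  wf <- if (n_valid > 0) (wins_plus + timeout_plus) / n_valid else NaN
  tibble::tibble(
    reps = reps, wins_plus = wins_plus, wins_minus = wins_minus,
    timeout_plus = timeout_plus, timeout_minus = timeout_minus,
    ties = ties, both_extinct = both_extinct, n_valid = n_valid,
    win_fraction = wf, se = binom_se(wf, n_valid))
}

#' Largest tolerated PCD rate
#'
#' Scans an ascending grid of PCD probabilities and reports the largest one
#' at which the PCD+ strain still wins a majority of competitions
#' (`win_fraction > 0.5`); 0 when no grid value is favoured.
#'
#' @inheritParams win_fraction_sweep
#' @param pcd_grid Ascending vector of PCD probabilities to scan.
#' @return A list with `max_pcd` (the largest favoured PCD rate, 0 if none)
#'   and `sweep` (the per-rate win-fraction tibble).
#' @examples
#' max_tolerated_pcd(disaster_prob = 0.1, assortment = 0.9,
#'                   pcd_grid = c(0.02, 0.1), reps = 4, capacity = 200,
#'                   max_rounds = 200, seed = 1)
#' @export
max_tolerated_pcd <- function(disaster_prob, assortment, switch_prob = 0.1,
                              pcd_grid, reps = 100, capacity = 10000,
                              max_rounds = 10000, seed = NULL) {
  if (is.unsorted(pcd_grid, strictly = TRUE)) {
    stop("`pcd_grid` must be strictly ascending", call. = FALSE)
  }
  sweep <- win_fraction_sweep(switch_prob = switch_prob,
                              pcd_prob = pcd_grid, assortment = assortment,
                              disaster_prob = disaster_prob, reps = reps,
                              capacity = capacity, max_rounds = max_rounds,
                              seed = seed)
  favoured <- sweep$pcd_prob[!is.nan(sweep$win_fraction) &
                               sweep$win_fraction > 0.5]
  list(max_pcd = if (length(favoured) > 0) max(favoured) else 0,
       sweep = sweep)
}
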