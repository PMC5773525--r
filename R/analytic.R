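# Closed-form layer: the deterministic one-round map and the cost/benefit
# theory it implies.  These functions are the oracle against which the
# stochastic models are validated.

#' Deterministic PCD/replacement round
#'
#' Advance the four real-valued counts of the spatially-implicit model one
#' round.  A fraction `pcd_prob` of each PCD+ phenotype dies; a fraction
#' `assortment` of the vacated spots is regrown by the PCD+ genotype itself
#' (same phenotype, switching with probability `switch_prob`) and the
#' remaining fraction goes to the PCD- competitor, split by its current
#' phenotype frequencies and then switched.  Total population is conserved.
#'
#' When the competitor is extinct its phenotype frequencies are undefined;
#' the convention used here returns the whole replacement flow to the PCD+
#' genotype (equivalent to `assortment = 1` while the competitor is absent),
#' because only living cells can regrow.
#'
#' @param state Four non-negative counts (`a_plus`, `b_plus`, `a_minus`,
#'   `b_minus`); real values allowed.
#' @param pcd_prob Per-round PCD probability `c` of the PCD+ strain.
#' @param assortment Fixed assortment `r`.
#' @param switch_prob Phenotype switch probability `p` (shared by both
#'   genotypes, as in the deterministic map).
#' @return A `population_state` advanced one round.
#' @examples
#' deterministic_round(population_state(25, 25, 25, 25),
#'                     pcd_prob = 0.1, assortment = 0, switch_prob = 0)
#' @export
deterministic_round <- function(state, pcd_prob, assortment, switch_prob) {
  x <- as_state(state)
  check_prob(pcd_prob, "pcd_prob")
  check_prob(assortment, "assortment")
  check_prob(switch_prob, "switch_prob")
  c_ <- pcd_prob; p <- switch_prob
  ap <- x[1]; bp <- x[2]; an <- x[3]; bn <- x[4]
  gn <- an + bn
  r_ <- if (gn == 0) 1 else assortment
  ap2 <- ap - c_ * ap + c_ * r_ * (1 - p) * ap + p * r_ * c_ * bp
  bp2 <- bp - c_ * bp + c_ * r_ * (1 - p) * bp + p * r_ * c_ * ap
  if (gn == 0) {
    an2 <- an
    bn2 <- bn
  } else {
    flow <- c_ * (ap + bp) * (1 - r_)
    fa <- an / gn
    fb <- bn / gn
    an2 <- an + flow * (fa * (1 - p) + fb * p)
    bn2 <- bn + flow * (fb * (1 - p) + fa * p)
  }
  population_state(ap2, bp2, an2, bn2)
}

#' Cost-of-PCD decay factor
#'
#' After `t` rounds of PCD and regrowth between disasters, the PCD+ genotype
#' total shrinks by the factor `(c (r - 1) + 1)^t`: each round it loses a
#' fraction `c (1 - r)` of its cells to the competitor.  At perfect
#' assortment (`assortment = 1`) the factor is 1 and PCD is costless.
#'
#' @inheritParams deterministic_round
#' @param rounds Non-negative number of PCD/regrowth rounds `t` between
#'   disasters.
#' @return The decay factor in `[0, 1]`; vectorised over its arguments.
#' @examples
#' cost_factor(0.1, 0.5, 2) # 0.95^2
#' cost_factor(0.1, 1, 50)  # no cost at perfect assortment
#' @export
cost_factor <- function(pcd_prob, assortment, rounds) {
  check_prob(pcd_prob, "pcd_prob")
  check_prob(assortment, "assortment")
  check_count(rounds, "rounds")
  (pcd_prob * (assortment - 1) + 1)^rounds
}

#' Expected numbers of switched offspring after one PCD/regrowth round
#'
#' Starting from `m` PCD+ cells, all of phenotype A (the situation right
#' after a disaster wiped phenotype B), one round of PCD and regrowth
#' produces on average `p r c m` B-phenotype cells of the PCD+ genotype and
#' `p (1 - r) c m` of the PCD- genotype.
#'
#' @inheritParams deterministic_round
#' @param m Number of PCD+ cells.
#' @return A tibble with columns `b_plus` and `b_minus` (expected counts).
#' @examples
#' expected_switch_counts(0.1, 0.5, 0.1, 100)
#' @export
expected_switch_counts <- function(switch_prob, assortment, pcd_prob, m) {
  check_prob(switch_prob, "switch_prob")
  check_prob(assortment, "assortment")
  check_prob(pcd_prob, "pcd_prob")
  check_count(m, "m", min = 1)
  tibble::tibble(
    b_plus = switch_prob * assortment * pcd_prob * m,
    b_minus = switch_prob * (1 - assortment) * pcd_prob * m)
}

#' Probability that only the PCD+ strain diversifies
#'
#' Probability that, in one PCD/regrowth round starting from `m` PCD+ cells
#' of a single phenotype, the PCD+ genotype produces at least one cell of
#' the alternate phenotype while the PCD- genotype produces none:
#' `(1 - p)^{cm(1 - r)} - (1 - p)^{cm}`.  The exponent `c m` is used as a
#' real number (an expectation), exactly as in the closed form.
#'
#' @inheritParams expected_switch_counts
#' @return A probability; vectorised.
#' @examples
#' prob_exclusive_diversification(0.01, 0.1, 100, 0.5)
#' @export
prob_exclusive_diversification <- function(switch_prob, pcd_prob, m,
                                           assortment) {
  check_prob(switch_prob, "switch_prob")
  check_prob(pcd_prob, "pcd_prob")
  check_prob(assortment, "assortment")
  check_count(m, "m", min = 1)
  n <- max(length(switch_prob), length(pcd_prob), length(m),
           length(assortment))
  p <- rep_len(switch_prob, n)
  cm <- rep_len(pcd_prob, n) * rep_len(m, n)
  r_ <- rep_len(assortment, n)
  pow <- function(q, e) ifelse(q == 0, ifelse(e == 0, 1, 0),
                               exp(e * log(q)))
  pow(1 - p, cm * (1 - r_)) - pow(1 - p, cm)
}

#' Switch probability maximising exclusive diversification
#'
#' The probability in [prob_exclusive_diversification()] is unimodal in the
#' switch probability, with its interior maximum at
#' `p* = 1 - (1 - r)^{1 / (c m r)}`.  For small assortment this corresponds
#' to roughly one expected switched-at-replacement offspring
#' (`p* c m` near 1).  At `assortment = 1` the maximiser degenerates to
#' `p* = 1` (the limit of the closed form), which is returned.
#'
#' @inheritParams expected_switch_counts
#' @return The optimal switch probability; vectorised.
#' @examples
#' optimal_switch_rate(0.1, 100, 0.5) # 1 - 0.5^0.2
#' @export
optimal_switch_rate <- function(pcd_prob, m, assortment) {
  check_prob(pcd_prob, "pcd_prob")
  check_prob(assortment, "assortment")
  check_count(m, "m", min = 1)
  if (any(pcd_prob * m * assortment == 0)) {
    stop("`pcd_prob * m * assortment` must be positive", call. = FALSE)
  }
  n <- max(length(pcd_prob), length(m), length(assortment))
  cm <- rep_len(pcd_prob, n) * rep_len(m, n)
  r_ <- rep_len(assortment, n)
  ifelse(r_ == 1, 1, -expm1(log1p(-r_) / (cm * r_)))
}

#' Probability the PCD+ strain is wiped out by its own PCD
#'
#' All `m` PCD+ cells must die by PCD in the same round and every one must
#' be replaced by the competing strain: `c^m (1 - r)^m`.
#'
#' @inheritParams expected_switch_counts
#' @return A probability; vectorised.
#' @examples
#' prob_pcd_extinction(0.5, 4, 0.5) # 0.25^4
#' @export
prob_pcd_extinction <- function(pcd_prob, m, assortment) {
  check_prob(pcd_prob, "pcd_prob")
  check_prob(assortment, "assortment")
  check_count(m, "m", min = 1)
  (pcd_prob * (1 - assortment))^m
}

#' Benefit-to-cost ratio of PCD
#'
#' Ratio of the exclusive-diversification probability to the
#' PCD-extinction probability,
#' `(1 - p)^{cm} ((1 - p)^{-cmr} - 1) / (c (1 - r))^m`, computed in log
#' space with an `expm1` step so that switch probabilities as small as
#' `1e-6` do not suffer catastrophic cancellation.  A zero denominator
#' (`pcd_prob = 0` or `assortment = 1`) is reported as `Inf` (PCD cannot
#' cost extinction there).
#'
#' @inheritParams expected_switch_counts
#' @param log10 Return the base-10 logarithm of the ratio instead.
#' @return The ratio (or its log10); vectorised.
#' @examples
#' benefit_cost_ratio(1e-6, 0.09, 11, 0.5, log10 = TRUE)
#' @export
benefit_cost_ratio <- function(switch_prob, pcd_prob, m, assortment,
                               log10 = FALSE) {
  check_prob(switch_prob, "switch_prob")
  check_prob(pcd_prob, "pcd_prob")
  check_prob(assortment, "assortment")
  check_count(m, "m", min = 1)
  n <- max(length(switch_prob), length(pcd_prob), length(m),
           length(assortment))
  p <- rep_len(switch_prob, n)
  c_ <- rep_len(pcd_prob, n)
  m_ <- rep_len(m, n)
  r_ <- rep_len(assortment, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (c_[i] == 0 || r_[i] == 1) {
      out[i] <- Inf
    } else if (p[i] == 0 || p[i] == 1) {
      out[i] <- if (log10) -Inf else 0
    } else {
      l1p <- log1p(-p[i])
      lnum <- c_[i] * m_[i] * l1p + log(expm1(-c_[i] * m_[i] * r_[i] * l1p))
      lden <- m_[i] * (log(c_[i]) + log1p(-r_[i]))
      out[i] <- if (log10) (lnum - lden) / log(10) else exp(lnum - lden)
    }
  }
  out
}

#' Generations to reach maximal phenotypic diversity
#'
#' For a clonal population switching phenotype with probability
#' `switch_prob` per reproduction, the expected minority-phenotype frequency
#' follows `x_{t+1} = x_t (1 - p) + (1 - x_t) p` and approaches the 50:50
#' stationary point geometrically.  Starting from a uniform population
#' (`x = 0`), this returns the first generation at which `0.5 - x <= tol`,
#' which equals `ceiling(log(2 tol) / log(1 - 2p))` for `p < 0.5`.  The
#' default tolerance, 0.005, is 1% of the stationary frequency.
#'
#' @param switch_prob Switch probability `p` in `(0, 0.5]`.
#' @param tol Positive tolerance below 0.5 on the distance to the
#'   stationary minority frequency.
#' @return Integer number of generations.
#' @examples
#' time_to_stationary_diversity(1e-3)  # > 1000 generations
#' @export
time_to_stationary_diversity <- function(switch_prob, tol = 0.005) {
  if (!is.numeric(switch_prob) || length(switch_prob) != 1 ||
      switch_prob <= 0 || switch_prob > 0.5) {
    stop("`switch_prob` must be in (0, 0.5]", call. = FALSE)
  }
  if (!is.numeric(tol) || length(tol) != 1 || tol <= 0 || tol >= 0.5) {
    stop("`tol` must be in (0, 0.5): at tol >= 0.5 the criterion holds ",
         "before any switching", call. = FALSE)
  }
  x <- 0
  t <- 0L
  while (0.5 - x > tol) {
    x <- x * (1 - switch_prob) + (1 - x) * switch_prob
    t <- t + 1L
    if (t > 1e8) stop("iteration failed to converge", call. = FALSE)
  }
  t
}

#' Evaluate the closed-form quantities on a parameter grid
#'
#' Builds the full crossing of the supplied parameter vectors and evaluates
#' one of the closed-form quantities on every combination.
#'
#' @param quantity One of `"cost_factor"`, `"exclusive_diversification"`,
#'   `"pcd_extinction"`, `"benefit_cost_ratio"`, `"optimal_switch_rate"`,
#'   `"switch_counts"`.
#' @param switch_prob,pcd_prob,assortment,m,rounds Parameter vectors; only
#'   those used by `quantity` are required.
#' @return A tibble with one row per parameter combination and a `value`
#'   column (two columns for `"switch_counts"`).
#' @examples
#' analytic_grid("cost_factor", pcd_prob = c(0.05, 0.1),
#'               assortment = c(0.5, 1), rounds = 10)
#' @export
analytic_grid <- function(quantity = c("cost_factor",
                                       "exclusive_diversification",
                                       "pcd_extinction",
                                       "benefit_cost_ratio",
                                       "optimal_switch_rate",
                                       "switch_counts"),
                          switch_prob = NULL, pcd_prob = NULL,
                          assortment = NULL, m = NULL, rounds = NULL) {
  quantity <- match.arg(quantity)
  need <- switch(quantity,
    cost_factor = c("pcd_prob", "assortment", "rounds"),
    exclusive_diversification = c("switch_prob", "pcd_prob", "m",
                                  "assortment"),
    pcd_extinction = c("pcd_prob", "m", "assortment"),
    benefit_cost_ratio = c("switch_prob", "pcd_prob", "m", "assortment"),
    optimal_switch_rate = c("pcd_prob", "m", "assortment"),
    switch_counts = c("switch_prob", "assortment", "pcd_prob", "m"))
  supplied <- list(switch_prob = switch_prob, pcd_prob = pcd_prob,
                   assortment = assortment, m = m, rounds = rounds)
  missing <- setdiff(need, names(supplied)[!vapply(supplied, is.null,
                                                   logical(1))])
  if (length(missing) > 0) {
    stop("`", quantity, "` needs parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  grid <- tidyr::crossing(!!!supplied[need])
  out <- switch(quantity,
    cost_factor = dplyr::mutate(grid, value = cost_factor(
      .data$pcd_prob, .data$assortment, .data$rounds)),
    exclusive_diversification = dplyr::mutate(grid,
      value = prob_exclusive_diversification(.data$switch_prob,
        .data$pcd_prob, .data$m, .data$assortment)),
    pcd_extinction = dplyr::mutate(grid, value = prob_pcd_extinction(
      .data$pcd_prob, .data$m, .data$assortment)),
    benefit_cost_ratio = dplyr::mutate(grid, value = benefit_cost_ratio(
      .data$switch_prob, .data$pcd_prob, .data$m, .data$assortment)),
    optimal_switch_rate = dplyr::mutate(grid, value = optimal_switch_rate(
      .data$pcd_prob, .data$m, .data$assortment)),
    switch_counts = dplyr::bind_cols(grid, expected_switch_counts(
      grid$switch_prob, grid$assortment, grid$pcd_prob, grid$m)))
  tibble::as_tibble(out)
}
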