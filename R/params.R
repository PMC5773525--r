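#' Strain parameters
#'
#' Bundle one genotype's probabilities: the stochastic phenotype switch
#' probability `switch_prob` (per reproduction, the offspring takes the
#' alternate phenotype with this probability) and the per-round programmed
#' cell death probability `pcd_prob`.  A PCD- strain must have
#' `pcd_prob = 0`.
#'
#' @param switch_prob Probability in `[0, 1]` that an offspring switches
#'   phenotype at reproduction.
#' @param pcd_prob Probability in `[0, 1]` that a cell of this strain dies
#'   by programmed cell death in one round.
#' @param pcd_plus Logical; whether this is the PCD+ genotype.  Defaults to
#'   `pcd_prob > 0`.
#' @return A list of class `"strain_params"`.
#' @examples
#' strain_params(0.1, 0.05)
#' strain_params(0.1, 0, pcd_plus = FALSE)
#' @export
strain_params <- function(switch_prob, pcd_prob = 0,
                          pcd_plus = pcd_prob > 0) {
  check_prob(switch_prob, "switch_prob")
  check_prob(pcd_prob, "pcd_prob")
  if (!pcd_plus && pcd_prob > 0) {
    stop("a PCD- strain must have `pcd_prob = 0`", call. = FALSE)
  }
  structure(list(switch_prob = switch_prob, pcd_prob = pcd_prob,
                 pcd_plus = isTRUE(pcd_plus)),
            class = "strain_params")
}

#' Environment parameters
#'
#' @param disaster_prob Per-round probability `d` that a disaster strikes a
#'   uniformly chosen phenotype.
#' @param kill_fraction Fraction of the targeted phenotype killed by a
#'   disaster (1 in the well-mixed and lattice models, 0.99 in the
#'   agent-based model).
#' @param capacity Carrying capacity `N` (total population, or per patch in
#'   the agent-based model).
#' @param assortment Fixed assortment probability `r` (spatially-implicit
#'   model only): the probability that a cell dying from PCD is replaced by
#'   growth from its own genotype.
#' @return A list of class `"environment_params"`.
#' @examples
#' environment_params(0.1, capacity = 10000, assortment = 0.9)
#' @export
environment_params <- function(disaster_prob, kill_fraction = 1,
                               capacity = 10000, assortment = 0.5) {
  check_prob(disaster_prob, "disaster_prob")
  check_prob(kill_fraction, "kill_fraction")
  check_prob(assortment, "assortment")
  check_count(capacity, "capacity", min = 2)
  structure(list(disaster_prob = disaster_prob,
                 kill_fraction = kill_fraction,
                 capacity = capacity, assortment = assortment),
            class = "environment_params")
}

#' Population state for the spatially-implicit model
#'
#' Four non-negative counts: phenotype A and B of the PCD+ genotype, then of
#' the PCD- genotype.
#'
#' @param a_plus,b_plus,a_minus,b_minus Non-negative counts.
#' @return A named numeric vector with class `"population_state"`.
#' @examples
#' population_state(2500, 2500, 2500, 2500)
#' @export
population_state <- function(a_plus, b_plus, a_minus, b_minus) {
  x <- c(a_plus = a_plus, b_plus = b_plus, a_minus = a_minus,
         b_minus = b_minus)
  if (anyNA(x) || any(x < 0)) {
    stop("population counts must be non-negative", call. = FALSE)
  }
  structure(x, class = "population_state")
}

as_state <- function(state) {
  x <- unclass(state)
  if (!is.numeric(x) || length(x) != 4 || anyNA(x) || any(x < 0)) {
    stop("`state` must be four non-negative counts ",
         "(a_plus, b_plus, a_minus, b_minus)", call. = FALSE)
  }
  unname(x)
}

as_int_state <- function(state) {
  x <- as_state(state)
  if (any(x != floor(x))) {
    stop("stochastic operations require integer counts", call. = FALSE)
  }
  as.integer(x)
}

state_out <- function(x) {
  population_state(x[1], x[2], x[3], x[4])
}

#' @export
print.population_state <- function(x, ...) {
  cat("<population_state>  total", sum(x), "\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}
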