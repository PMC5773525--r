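# Spatially-implicit stochastic model.

test_that("pcd_regrowth_round conserves cells and respects edge cases", {
  st <- population_state(50, 50, 50, 50)
  expect_equal(pcd_regrowth_round(st, pcd_prob = 0, assortment = 0.5,
                                  p_plus = 0.3), st)
  set.seed(1)
  for (k in 1:50) {
    out <- pcd_regrowth_round(st, pcd_prob = runif(1),
                              assortment = runif(1), p_plus = runif(1),
                              p_minus = runif(1))
    expect_identical(sum(out), 200L)
    expect_true(all(out >= 0))
  }
  # full assortment without switching keeps both genotype totals fixed
  set.seed(2)
  for (k in 1:25) {
    out <- pcd_regrowth_round(st, pcd_prob = 0.5, assortment = 1,
                              p_plus = 0)
    expect_equal(genotype_totals(out), genotype_totals(st))
  }
  expect_error(pcd_regrowth_round(population_state(0, 0, 0, 0), 0.1, 0.5,
                                  0.1), "empty")
})

test_that("mean of stochastic rounds matches the deterministic map", {
  # 3-SE componentwise criterion at three parameter points
  pts <- list(
    list(st = population_state(50, 50, 50, 50), c = 0.1, r = 0.6, p = 0.05),
    list(st = population_state(120, 30, 20, 30), c = 0.2, r = 0.9, p = 0.1),
    list(st = population_state(40, 80, 60, 20), c = 0.05, r = 0.2,
         p = 0.01))
  set.seed(3)
  for (pt in pts) {
    draws <- vapply(seq_len(1e4), function(i)
      as.numeric(pcd_regrowth_round(pt$st, pt$c, pt$r, pt$p)), numeric(4))
    expected <- as.numeric(deterministic_round(pt$st, pt$c, pt$r, pt$p))
    for (j in 1:4) {
      se <- stats::sd(draws[j, ]) / sqrt(ncol(draws))
      expect_lt(abs(mean(draws[j, ]) - expected[j]), 3 * max(se, 1e-9))
    }
  }
})

test_that("apply_disaster annihilates or binomially thins the target", {
  st <- population_state(30, 20, 40, 10)
  expect_equal(apply_disaster(st, "A", kill_fraction = 1),
               population_state(0, 20, 0, 10))
  expect_equal(apply_disaster(st, "B", kill_fraction = 0), st)
  set.seed(4)
  surv <- vapply(seq_len(4000), function(i)
    apply_disaster(population_state(100, 0, 0, 0), "A",
                   kill_fraction = 0.99)[["a_plus"]], numeric(1))
  se <- stats::sd(surv) / sqrt(length(surv))
  expect_lt(abs(mean(surv) - 1), 3 * se)
})

test_that("regrow_to_capacity restores N with urn-style inheritance", {
  # no switching: clonal regrowth
  out <- regrow_to_capacity(population_state(10, 0, 0, 0), p_plus = 0,
                            capacity = 100, seed = 5)
  expect_equal(out, population_state(100, 0, 0, 0))
  st <- population_state(25, 25, 25, 25)
  expect_equal(regrow_to_capacity(st, p_plus = 0.1, capacity = 100), st)
  expect_error(regrow_to_capacity(population_state(0, 0, 0, 0), 0.1,
                                  capacity = 10), "extinct")

  # single birth switches with exactly the genotype's probability
  set.seed(6)
  draws <- vapply(seq_len(4000), function(i)
    regrow_to_capacity(population_state(1, 0, 0, 0), p_plus = 0.5,
                       capacity = 2)[["b_plus"]], numeric(1))
  expect_lt(abs(mean(draws) - 0.5), 3 * stats::sd(draws) / sqrt(4000))

  # full urn against the conditional-expectation recursion oracle
  set.seed(7)
  draws <- vapply(seq_len(1e4), function(i)
    regrow_to_capacity(population_state(10, 0, 0, 0), p_plus = 0.01,
                       capacity = 100)[["b_plus"]], numeric(1))
  expected <- urn_expected_switched(10, 100, 0.01)
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected), 3 * se)

  # few births from a large base: compounding is negligible, so the final
  # switched count is the per-birth switching expectation p * (N - m)
  set.seed(77)
  draws <- vapply(seq_len(1e4), function(i)
    regrow_to_capacity(population_state(50, 0, 0, 0), p_plus = 0.1,
                       capacity = 55)[["b_plus"]], numeric(1))
  expected_few <- urn_expected_switched(50, 55, 0.1)
  expect_lt(abs(expected_few - 0.1 * 5) / 0.5, 0.05)
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected_few), 3 * se)
})

test_that("run_competition is deterministic given a seed and keeps N", {
  a <- run_competition(capacity = 400, max_rounds = 300, seed = 8)
  b <- run_competition(capacity = 400, max_rounds = 300, seed = 8)
  expect_identical(tidy(a), tidy(b))
  expect_identical(glance(a), glance(b))
  tr <- tidy(a)
  totals <- tr$a_plus + tr$b_plus + tr$a_minus + tr$b_minus
  expect_true(all(totals == 400 | totals == 0))
})

test_that("without disasters the PCD+ strain loses", {
  cmp <- run_competition(p_plus = 0.1, pcd_prob = 0.05, assortment = 0.5,
                         disaster_prob = 0, capacity = 2000,
                         max_rounds = 10000, record_trajectory = FALSE,
                         seed = 9)
  expect_true(cmp$winner %in% c("PCD-", "timeout_majority_PCD-"))
})

test_that("neutral competitions are symmetric under genotype relabelling", {
  # both strains identical (no PCD): wins split within the binomial 99% CI
  wins <- 0L; valid <- 0L
  for (i in seq_len(300)) {
    cmp <- run_competition(p_plus = 0.1, p_minus = 0.1, pcd_prob = 0,
                           assortment = 0.5, disaster_prob = 0.2,
                           capacity = 500, max_rounds = 400,
                           record_trajectory = FALSE, seed = 100 + i)
    if (cmp$winner %in% c("PCD+", "timeout_majority_PCD+")) {
      wins <- wins + 1L; valid <- valid + 1L
    } else if (cmp$winner %in% c("PCD-", "timeout_majority_PCD-")) {
      valid <- valid + 1L
    }
  }
  ci <- stats::binom.test(wins, valid, 0.5)$p.value
  expect_gt(ci, 0.01)
})

test_that("win_fraction_sweep tallies outcomes consistently", {
  sw <- win_fraction_sweep(switch_prob = 0.1, pcd_prob = 0.05,
                           assortment = 0.9, disaster_prob = 0.1,
                           reps = 6, capacity = 200, max_rounds = 100,
                           seed = 10)
  expect_identical(nrow(sw), 1L)
  expect_identical(
    sw$wins_plus + sw$wins_minus + sw$timeout_plus + sw$timeout_minus +
      sw$ties + sw$both_extinct, 6L)
  # a one-replicate sweep reduces to a single run_competition outcome
  sw1 <- win_fraction_sweep(switch_prob = 0.1, pcd_prob = 0.05,
                            assortment = 0.9, disaster_prob = 0.1,
                            reps = 1, capacity = 200, max_rounds = 100,
                            seed = 10)
  cmp <- run_competition(p_plus = 0.1, pcd_prob = 0.05, assortment = 0.9,
                         disaster_prob = 0.1, capacity = 200,
                         max_rounds = 100, record_trajectory = FALSE,
                         seed = pcdbet:::child_seed(10, 1, 1))
  cls <- c("PCD+" = "wins_plus", "PCD-" = "wins_minus",
           "timeout_majority_PCD+" = "timeout_plus",
           "timeout_majority_PCD-" = "timeout_minus",
           "timeout_tie" = "ties", "both_extinct" = "both_extinct")
  expect_identical(sw1[[cls[[cmp$winner]]]], 1L)
})

test_that("max_tolerated_pcd returns the 0 sentinel without disasters", {
  mt <- max_tolerated_pcd(disaster_prob = 0, assortment = 0.5,
                          pcd_grid = c(0.05, 0.1), reps = 4,
                          capacity = 400, max_rounds = 1500, seed = 11)
  expect_identical(mt$max_pcd, 0)
  expect_error(max_tolerated_pcd(0.1, 0.5, pcd_grid = c(0.1, 0.05),
                                 reps = 2, capacity = 100,
                                 max_rounds = 10), "ascending")
})
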