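# Closed-form layer: the deterministic map and the cost/benefit formulas.

test_that("deterministic_round reproduces hand-evaluated states", {
  # equal quarters, no switching, no assortment: PCD+ loses c*G_p = 5 cells,
  # split equally between the competitor's phenotypes
  out <- deterministic_round(population_state(25, 25, 25, 25),
                             pcd_prob = 0.1, assortment = 0, switch_prob = 0)
  expect_equal(unname(unclass(out)), c(22.5, 22.5, 27.5, 27.5))

  # full assortment, no switching: every death replaced in kind
  st <- population_state(40, 10, 30, 20)
  out <- deterministic_round(st, pcd_prob = 0.3, assortment = 1,
                             switch_prob = 0)
  expect_equal(unclass(out), unclass(st))

  # independent term-by-term hand evaluation, frozen values
  out <- deterministic_round(st, pcd_prob = 0.05, assortment = 0.6,
                             switch_prob = 0.01)
  expect_equal(unname(unclass(out)), c(39.191, 9.809, 30.598, 20.402),
               tolerance = 1e-12)
  expect_equal(sum(out), 100)
})

test_that("deterministic_round conserves the total and follows the cost law", {
  set.seed(11)
  for (k in 1:25) {
    st <- population_state(runif(1, 0, 500), runif(1, 0, 500),
                           runif(1, 0, 500), runif(1, 0, 500))
    c_ <- runif(1); r_ <- runif(1); p_ <- runif(1)
    out <- deterministic_round(st, c_, r_, p_)
    expect_equal(sum(out), sum(st), tolerance = 1e-12)
    # per-round genotype flow: delta G_p = -c (1 - r) G_p = -delta G_n
    g0 <- genotype_totals(st); g1 <- genotype_totals(out)
    expect_equal(g1[["plus"]] - g0[["plus"]], -c_ * (1 - r_) * g0[["plus"]],
                 tolerance = 1e-10)
  }
})

test_that("competitor-extinct rounds keep all regrowth in the PCD+ strain", {
  st <- population_state(60, 40, 0, 0)
  out <- deterministic_round(st, pcd_prob = 0.2, assortment = 0.3,
                             switch_prob = 0.1)
  expect_equal(sum(out), 100)
  expect_equal(genotype_totals(out)[["minus"]], 0)
  expect_error(deterministic_round(c(-1, 2, 3, 4), 0.1, 0.5, 0),
               "non-negative")
})

test_that("cost_factor matches its closed form and repeated rounds", {
  expect_equal(cost_factor(0.1, 1, 5), 1)
  expect_equal(cost_factor(0, 0.5, 10), 1)
  expect_equal(cost_factor(0.1, 0.5, 2), 0.9025)

  # t applications of the deterministic map scale G_p by the factor
  set.seed(21)
  for (k in 1:10) {
    c_ <- runif(1); r_ <- runif(1); p_ <- runif(1); t_ <- sample(1:20, 1)
    st <- population_state(100, 50, 200, 150)
    cur <- st
    for (i in seq_len(t_)) cur <- deterministic_round(cur, c_, r_, p_)
    expect_equal(genotype_totals(cur)[["plus"]],
                 genotype_totals(st)[["plus"]] * cost_factor(c_, r_, t_),
                 tolerance = 1e-10)
  }

  # monotone: non-increasing in pcd rate and rounds, non-decreasing in r
  cs <- seq(0, 1, by = 0.1); rs <- seq(0, 1, by = 0.1); ts <- c(0, 1, 5, 50)
  for (t_ in ts) {
    for (r_ in rs) expect_true(all(diff(cost_factor(cs, r_, t_)) <= 1e-15))
    for (c_ in cs) expect_true(all(diff(cost_factor(c_, rs, t_)) >= -1e-15))
  }
  for (c_ in cs) for (r_ in rs) {
    expect_true(all(diff(cost_factor(c_, r_, ts)) <= 1e-15))
  }
})

test_that("expected switch counts match the closed form and the stochastic round", {
  expect_equal(expected_switch_counts(0.1, 0.5, 0.1, 100),
               tibble::tibble(b_plus = 0.5, b_minus = 0.5))
  expect_equal(expected_switch_counts(0.1, 1, 0.1, 100),
               tibble::tibble(b_plus = 1, b_minus = 0))

  # Monte-Carlo oracle: one stochastic PCD/regrowth round starting from
  # m PCD+ cells and a competitor, all phenotype A
  p <- 0.01; r_ <- 0.75; c_ <- 0.05; m <- 200
  st <- population_state(m, 0, 300, 0)
  set.seed(31)
  draws <- vapply(seq_len(2e4), function(i) {
    out <- pcd_regrowth_round(st, pcd_prob = c_, assortment = r_,
                              p_plus = p, p_minus = p)
    c(out[["b_plus"]], out[["b_minus"]])
  }, numeric(2))
  exp_counts <- expected_switch_counts(p, r_, c_, m)
  for (i in 1:2) {
    se <- stats::sd(draws[i, ]) / sqrt(ncol(draws))
    expect_lt(abs(mean(draws[i, ]) - c(exp_counts$b_plus,
                                       exp_counts$b_minus)[i]), 3 * se)
  }
})

test_that("exclusive diversification probability behaves per the closed form", {
  expect_equal(prob_exclusive_diversification(0, 0.1, 100, 0.5), 0)
  expect_equal(prob_exclusive_diversification(0.3, 0.1, 100, 0), 0)
  expect_equal(prob_exclusive_diversification(0.01, 0.1, 100, 0.5),
               0.99^5 - 0.99^10)

  # unimodal in p with interior maximum at the optimal switch rate
  for (par in list(c(0.1, 100, 0.5), c(0.05, 200, 0.75),
                   c(0.5, 40, 0.2))) {
    ps <- seq(1e-4, 0.9999, length.out = 20000)
    vals <- prob_exclusive_diversification(ps, par[1], par[2], par[3])
    p_star <- optimal_switch_rate(par[1], par[2], par[3])
    expect_lt(abs(ps[which.max(vals)] - p_star), 1e-3)
    # single interior maximum: increasing then decreasing
    d <- diff(vals)
    expect_equal(rle(d > 0)$values, c(TRUE, FALSE))
  }
})

test_that("optimal switch rate matches its closed form and the one-B reading", {
  expect_equal(optimal_switch_rate(0.1, 100, 0.5), 1 - 0.5^0.2)
  # for small assortment, p* c m is near one expected switched offspring
  p_star <- optimal_switch_rate(0.5, 200, 0.01)
  expect_lt(abs(p_star * 0.5 * 200 - 1), 0.1)
  expect_error(optimal_switch_rate(0, 100, 0.5), "positive")
})

test_that("PCD-extinction probability matches its closed form", {
  expect_equal(prob_pcd_extinction(0.7, 5, 1), 0)
  expect_equal(prob_pcd_extinction(1, 5, 0), 1)
  expect_equal(prob_pcd_extinction(0.5, 4, 0.5), 0.00390625)
})

test_that("benefit_cost_ratio is stable and equals the probability ratio", {
  expect_gt(benefit_cost_ratio(1e-6, 0.09, 11, 0.5, log10 = TRUE), 6)
  expect_identical(benefit_cost_ratio(0.1, 0, 10, 0.5), Inf)
  expect_identical(benefit_cost_ratio(0.1, 0.5, 10, 1), Inf)
  # vanishing switch rate: benefit vanishes, cost fixed
  expect_equal(benefit_cost_ratio(0, 0.5, 10, 0.5), 0)
  expect_lt(benefit_cost_ratio(1e-12, 0.5, 10, 0.5), 1e-4)
  expect_lt(benefit_cost_ratio(1e-12, 0.5, 10, 0.5),
            benefit_cost_ratio(1e-8, 0.5, 10, 0.5))

  set.seed(41)
  for (k in 1:50) {
    p <- runif(1, 1e-4, 0.5); c_ <- runif(1, 0.05, 0.9)
    m <- sample(3:20, 1); r_ <- runif(1, 0.1, 0.9)
    lhs <- log(benefit_cost_ratio(p, c_, m, r_))
    rhs <- log(prob_exclusive_diversification(p, c_, m, r_) /
                 prob_pcd_extinction(c_, m, r_))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("time to stationary diversity matches iteration and closed form", {
  expect_identical(time_to_stationary_diversity(0.5, 0.01), 1L)
  t <- time_to_stationary_diversity(1e-3, 0.005)
  expect_identical(t, 2301L)
  expect_identical(t, as.integer(ceiling(log(2 * 0.005) / log(1 - 2e-3))))
  expect_gt(t, 1000)
  expect_error(time_to_stationary_diversity(1e-3, 0.6), "tol")
  expect_error(time_to_stationary_diversity(0.7), "switch_prob")
})

test_that("analytic_grid crosses parameters and rejects missing ones", {
  g <- analytic_grid("cost_factor", pcd_prob = c(0.05, 0.1),
                     assortment = c(0.5, 1), rounds = c(1, 10))
  expect_identical(nrow(g), 8L)
  expect_equal(g$value, cost_factor(g$pcd_prob, g$assortment, g$rounds))
  expect_error(analytic_grid("benefit_cost_ratio", pcd_prob = 0.1),
               "needs parameter")
})
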