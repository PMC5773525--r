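# 2D spatially-explicit model with emergent assortment.

test_that("init_lattice hits attainable targets and fails cleanly otherwise", {
  g <- init_lattice(0.5, rows = 100, cols = 100, seed = 1)
  expect_identical(sort(unique(as.vector(g))), 1:4)
  n_plus <- sum(g %in% 1:2); n_minus <- sum(g %in% 3:4)
  expect_lte(abs(n_plus - n_minus), 1)
  expect_lt(abs(measure_assortment(g)$mean_r - 0.5), 0.02)

  g95 <- init_lattice(0.95, rows = 100, cols = 100, seed = 2)
  expect_gte(measure_assortment(g95)$mean_r, 0.93)
  expect_lte(abs(sum(g95 %in% 1:2) - sum(g95 %in% 3:4)), 1)

  # anti-assorted targets below the attainable floor must fail, naming the
  # assortment achieved
  expect_error(init_lattice(0.2, rows = 30, cols = 30, max_iter = 20000,
                            seed = 3), "achieved")
})

test_that("measure_assortment matches hand enumeration on 3x3 fixtures", {
  # one PCD+ cell surrounded by PCD-
  s <- measure_assortment(lat3_center_plus())
  expect_identical(s$mean_r, 0)
  expect_identical(s$n_cells, 1L)

  # all PCD+
  expect_identical(measure_assortment(matrix(1L, 3, 3))$mean_r, 1)

  # mixed fixture: centre PCD+ with 4 PCD+ / 4 PCD- neighbours; corner and
  # edge PCD+ cells enumerated by hand over their 3 or 5 neighbours
  g <- matrix(c(1L, 3L, 1L,
                3L, 1L, 3L,
                1L, 3L, 1L), 3, 3, byrow = TRUE)
  s <- measure_assortment(g, per_cell = TRUE)
  expect_identical(s$n_cells, 5L)
  centre <- s$per_cell$r[s$per_cell$row == 2 & s$per_cell$col == 2]
  expect_identical(centre, 4 / 8)
  corners <- s$per_cell$r[s$per_cell$row != 2]
  expect_true(all(corners == 1 / 3))
  expect_equal(s$mean_r, (4 / 8 + 4 * (1 / 3)) / 5)
  expect_equal(s$mean_r, measure_r_bruteforce(g))

  # no PCD+ cells: flagged undefined
  s <- measure_assortment(matrix(3L, 3, 3))
  expect_true(s$undefined)
  expect_true(is.na(s$mean_r))
})

test_that("compiled assortment estimator agrees with brute force", {
  set.seed(5)
  for (k in 1:10) {
    g <- matrix(sample(0:4, 64, replace = TRUE), 8, 8)
    storage.mode(g) <- "integer"
    expect_equal(measure_assortment(g)$mean_r, measure_r_bruteforce(g))
  }
})

test_that("random 50:50 lattices measure near one half", {
  set.seed(6)
  g <- matrix(sample(rep(1:4, 2500)), 100, 100)
  storage.mode(g) <- "integer"
  expect_lt(abs(measure_assortment(g)$mean_r - 0.5), 0.02)
})

test_that("repopulation fills the lattice from living neighbours", {
  g <- matrix(1L, 4, 4)
  expect_identical(repopulate_lattice(g, p_plus = 0), g)

  # one empty site with a single living neighbour: deterministic copy
  g1 <- matrix(0L, 2, 2); g1[1, 1] <- 4L
  out <- repopulate_lattice(g1, p_plus = 0, p_minus = 0, seed = 7)
  expect_true(all(out == 4L))

  # never stalls while a living cell exists; with no switching never
  # creates a phenotype absent from the survivors
  set.seed(8)
  for (k in 1:10) {
    g <- matrix(0L, 10, 10)
    g[sample(100, 5)] <- sample(c(1L, 3L), 5, replace = TRUE)
    out <- repopulate_lattice(g, p_plus = 0, p_minus = 0)
    expect_false(any(out == 0L))
    expect_true(all(out %in% c(1L, 3L)))
  }
  expect_error(repopulate_lattice(matrix(0L, 3, 3), 0.1), "living")
})

test_that("opposite-corner seeds fill symmetrically in expectation", {
  set.seed(9)
  diffs <- vapply(seq_len(200), function(i) {
    g <- matrix(0L, 15, 15)
    g[1, 1] <- 1L; g[15, 15] <- 3L
    out <- repopulate_lattice(g, p_plus = 0, p_minus = 0)
    sum(out == 1L) - sum(out == 3L)
  }, numeric(1))
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("lattice rounds conserve sites and log disasters", {
  g <- init_lattice(0.5, rows = 20, cols = 20, seed = 10)
  out <- lattice_round(g, pcd_prob = 0, disaster_prob = 0, p_plus = 0.1,
                       seed = 11)
  expect_identical(out$lattice, g)
  expect_false(out$log$disaster)

  # disaster annihilates one phenotype lattice-wide, then the lattice is
  # refilled completely
  out <- lattice_round(g, pcd_prob = 0.05, disaster_prob = 1, p_plus = 0.1,
                       previous_target = "A", seed = 12)
  expect_false(any(out$lattice == 0L))
  expect_true(out$log$disaster)
  expect_true(out$log$target %in% c("A", "B"))
  expect_identical(out$log$switched_target, out$log$target == "B")
  counts <- out$log$a_plus + out$log$b_plus + out$log$a_minus +
    out$log$b_minus
  expect_identical(counts, 400L)
})

test_that("repeated disasters never lower assortment in expectation", {
  set.seed(13)
  deltas <- vapply(seq_len(60), function(i) {
    g <- init_lattice(0.5, rows = 30, cols = 30)
    out <- lattice_round(g, pcd_prob = 0, disaster_prob = 1, p_plus = 0.1)
    out$log$delta_r
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("lattice competitions are deterministic and track genotype counts", {
  a <- run_lattice_competition(target_r = 0.5, rows = 20, cols = 20,
                               max_rounds = 60, seed = 14)
  b <- run_lattice_competition(target_r = 0.5, rows = 20, cols = 20,
                               max_rounds = 60, seed = 14)
  expect_identical(tidy(a), tidy(b))
  tr <- tidy(a)
  full_rows <- tr[tr$a_plus + tr$b_plus + tr$a_minus + tr$b_minus > 0, ]
  expect_true(all(full_rows$a_plus + full_rows$b_plus + full_rows$a_minus +
                    full_rows$b_minus == 400L))
  expect_true(all(full_rows$mean_r >= 0 & full_rows$mean_r <= 1))
})

test_that("neutral lattice competitions are symmetric over seeds", {
  wins <- 0L; valid <- 0L
  for (i in seq_len(60)) {
    cmp <- run_lattice_competition(target_r = 0.5, pcd_prob = 0,
                                   disaster_prob = 0.2, switch_prob = 0.1,
                                   rows = 20, cols = 20, max_rounds = 250,
                                   seed = 200 + i)
    if (cmp$winner %in% c("PCD+", "timeout_majority_PCD+")) {
      wins <- wins + 1L; valid <- valid + 1L
    } else if (cmp$winner %in% c("PCD-", "timeout_majority_PCD-")) {
      valid <- valid + 1L
    }
  }
  expect_gt(stats::binom.test(wins, valid, 0.5)$p.value, 0.01)
})

test_that("delta_r_statistics computes exact conditional means", {
  logs <- tibble::tibble(
    disaster = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    switched_target = c(NA, NA, NA, TRUE, TRUE, FALSE),
    delta_r = c(-0.001, -0.003, 0.05, 0.06, 0.10, -0.02))
  st <- delta_r_statistics(logs)
  expect_equal(st$mean_delta_r[st$class == "no_disaster"], -0.002)
  expect_equal(st$mean_delta_r[st$class == "disaster_switched"], 0.08)
  expect_equal(st$mean_delta_r[st$class == "disaster_repeat"], -0.02)
  # the first disaster (no previous target) belongs to neither class
  expect_identical(st$n[st$class == "disaster_switched"], 2L)

  empty <- delta_r_statistics(logs[logs$disaster, ])
  expect_identical(empty$n[empty$class == "no_disaster"], 0L)
  expect_true(is.na(empty$mean_delta_r[empty$class == "no_disaster"]))
  expect_error(delta_r_statistics(tibble::tibble(a = 1)), "columns")
})

test_that("lattice snapshots round-trip through plain text", {
  g <- init_lattice(0.75, rows = 8, cols = 12, seed = 15)
  txt <- format_lattice(g)
  expect_identical(length(txt), 8L)
  expect_true(all(nchar(txt) == 12L))
  path <- withr::local_tempfile()
  write_lattice(g, path)
  expect_identical(read_lattice(path), g)
})
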