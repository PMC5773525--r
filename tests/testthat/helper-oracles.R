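# Independent oracles and small fixtures used across the test files.

# Expected final count of switched-phenotype cells after sequentially
# regrowing an urn from `m` cells (all one phenotype, one genotype) to `n`,
# switching each birth with probability p: one-step conditional-expectation
# recursion, independent of the simulation code.
urn_expected_switched <- function(m, n, p) {
  b <- 0
  for (t in m:(n - 1)) {
    b <- b + b / t * (1 - p) + (1 - b / t) * p
  }
  b
}

# 3x3 lattice fixtures (codes: 0 empty, 1 A+, 2 B+, 3 A-, 4 B-)
lat3_center_plus <- function() {
  g <- matrix(3L, 3, 3)
  g[2, 2] <- 1L
  g
}

# mean lattice assortment by brute-force R enumeration (checks the compiled
# estimator)
measure_r_bruteforce <- function(g) {
  nr <- nrow(g); nc <- ncol(g)
  vals <- c()
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!(g[i, j] %in% c(1L, 2L))) next
      same <- 0; living <- 0
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        s <- g[ii, jj]
        if (s > 0L) {
          living <- living + 1
          if (s %in% c(1L, 2L)) same <- same + 1
        }
      }
      if (living > 0) vals <- c(vals, same / living)
    }
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

genotype_totals <- function(state) {
  x <- unclass(state)
  c(plus = unname(x[1] + x[2]), minus = unname(x[3] + x[4]))
}
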