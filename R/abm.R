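# 3D patch-structured agent-based model.  A world is a grid of patches,
# each holding at most `capacity` cells; assortment emerges from birth,
# death, migration and disaster bottlenecks.

#' Build a world of patches
#'
#' Places cells uniformly at random across the patch slots at the requested
#' fill fraction; genotypes follow the requested mix and phenotypes are
#' assigned A/B with probability 0.5.
#'
#' @param dims Integer vector of three patch-grid dimensions.
#' @param capacity Per-patch carrying capacity `K`.
#' @param fill_fraction Fraction of all slots initially occupied, in
#'   `(0, 1]`.
#' @param prop_plus Proportion of cells of the PCD+ genotype (0.5 for
#'   competitions; use `monoculture` for single-genotype worlds).
#' @param monoculture `NULL`, `"plus"` or `"minus"`: fill with one genotype
#'   only.
#' @param seed Optional integer seed.
#' @return An object of class `"pcd_world"`: a list with `counts` (patches
#'   x 4 integer matrix, columns `a_plus`, `b_plus`, `a_minus`,
#'   `b_minus`), `dims` and `capacity`.
#' @examples
#' w <- init_world(c(4, 4, 4), fill_fraction = 0.5, seed = 1)
#' compute_metrics(w)
#' @export
init_world <- function(dims = c(10, 10, 10), capacity = 10,
                       fill_fraction = 0.5, prop_plus = 0.5,
                       monoculture = NULL, seed = NULL) {
  check_count(dims, "dims", min = 1)
  if (length(dims) != 3) stop("`dims` must have length 3", call. = FALSE)
  check_count(capacity, "capacity", min = 1)
  if (!is.numeric(fill_fraction) || fill_fraction <= 0 ||
      fill_fraction > 1) {
    stop("`fill_fraction` must be in (0, 1]", call. = FALSE)
  }
  check_prob(prop_plus, "prop_plus")
  if (!is.null(monoculture)) {
    monoculture <- match.arg(monoculture, c("plus", "minus"))
    prop_plus <- if (monoculture == "plus") 1 else 0
  }
  n_patches <- prod(dims)
  n_slots <- n_patches * capacity
  n_cells <- round(fill_fraction * n_slots)
  if (n_cells < 1) stop("no cells requested", call. = FALSE)
  counts <- run_seeded(seed, {
    slots <- sample.int(n_slots, n_cells)
    patch <- (slots - 1L) %/% as.integer(capacity) + 1L
    n_plus <- round(n_cells * prop_plus)
    geno <- sample(rep(c(TRUE, FALSE), c(n_plus, n_cells - n_plus)))
    pheno_b <- runif(n_cells) < 0.5
    type <- 1L + (!geno) * 2L + pheno_b * 1L
    m <- matrix(0L, n_patches, 4)
    for (t in 1:4) {
      tb <- tabulate(patch[type == t], nbins = n_patches)
      m[, t] <- as.integer(tb)
    }
    m
  })
  colnames(counts) <- c("a_plus", "b_plus", "a_minus", "b_minus")
  structure(list(counts = counts, dims = as.integer(dims),
                 capacity = as.integer(capacity)), class = "pcd_world")
}

as_world <- function(world) {
  if (!inherits(world, "pcd_world")) {
    stop("`world` must be a `pcd_world` (see `init_world()`)",
         call. = FALSE)
  }
  if (any(rowSums(world$counts) > world$capacity)) {
    stop("a patch exceeds its capacity", call. = FALSE)
  }
  world
}

#' @export
print.pcd_world <- function(x, ...) {
  m <- compute_metrics(x)
  cat(sprintf("<pcd_world>  %s patches (K = %d), %d cells\n",
              paste(x$dims, collapse = " x "), x$capacity,
              m$a_plus + m$b_plus + m$a_minus + m$b_minus))
  print(m)
  invisible(x)
}

#' One agent-based model time step
#'
#' Phases in order: (1) with probability `disaster_prob` a uniformly chosen
#' phenotype loses `kill_fraction` of its cells in every patch (binomial
#' survivors); (2) reproduction: cells present at the start of the phase
#' each place one offspring into their own patch while it is below
#' capacity (when space is short the reproducing cells are a uniform random
#' subset), offspring switching phenotype with `switch_prob`; (3)
#' migration: each cell moves with probability `migration_prob` to a
#' uniformly chosen adjacent patch, staying put if the chosen patch is
#' full; (4) PCD: each PCD+ cell dies with probability `pcd_prob`.
#'
#' @param world A `pcd_world`.
#' @param disaster_prob Per-step disaster probability.
#' @param kill_fraction Fraction of the targeted phenotype killed by a
#'   disaster (0.99 by default).
#' @param switch_prob Per-reproduction phenotype switch probability.
#' @param migration_prob Per-cell per-step migration probability.
#' @param pcd_prob Per-step PCD probability of PCD+ cells.
#' @param neighbors Patch adjacency: 6 face neighbours (default) or 26.
#' @param seed Optional integer seed.
#' @return A list with the updated `world`, `disaster` (logical) and
#'   `target` (`"A"`, `"B"` or `NA`).
#' @examples
#' w <- init_world(c(3, 3, 3), fill_fraction = 0.4, seed = 1)
#' step <- abm_step(w, disaster_prob = 0, seed = 2)
#' @export
abm_step <- function(world, disaster_prob = 0.01, kill_fraction = 0.99,
                     switch_prob = 0.1, migration_prob = 0.005,
                     pcd_prob = 0.025, neighbors = 6, seed = NULL) {
  world <- as_world(world)
  check_prob(disaster_prob, "disaster_prob")
  check_prob(kill_fraction, "kill_fraction")
  check_prob(switch_prob, "switch_prob")
  check_prob(migration_prob, "migration_prob")
  check_prob(pcd_prob, "pcd_prob")
  neighbors <- match.arg(as.character(neighbors), c("6", "26"))
  res <- run_seeded(seed, abm_step_cpp(
    world$counts, world$dims, world$capacity, disaster_prob, kill_fraction,
    switch_prob, migration_prob, pcd_prob, neighbors == "26"))
  counts <- res$counts
  colnames(counts) <- colnames(world$counts)
  list(world = structure(list(counts = counts, dims = world$dims,
                              capacity = world$capacity),
                         class = "pcd_world"),
       disaster = res$disaster,
       target = decode_target(res$target))
}

#' Snapshot metrics of a world
#'
#' Global counts by type, per-genotype phenotypic diversity (the Shannon
#' entropy of the genotype's A/B split, normalised to `[0, 1]`; `NA` for an
#' absent genotype) and patch-level assortment: the mean over PCD+ cells
#' with at least one patch-mate of the same-genotype fraction among their
#' patch-mates (`NA` when no PCD+ cell qualifies).
#'
#' @param world A `pcd_world`.
#' @return A one-row tibble.
#' @examples
#' w <- init_world(c(3, 3, 3), fill_fraction = 1, seed = 1)
#' compute_metrics(w)
#' @export
compute_metrics <- function(world) {
  world <- as_world(world)
  res <- abm_metrics_cpp(world$counts)
  tibble::tibble(
    a_plus = res$counts[1], b_plus = res$counts[2],
    a_minus = res$counts[3], b_minus = res$counts[4],
    total = sum(res$counts),
    diversity_plus = res$diversity_plus,
    diversity_minus = res$diversity_minus,
    assortment = res$assortment)
}

#' Run the agent-based model
#'
#' Steps the world until a genotype present at initialisation goes extinct
#' (for monocultures: until the population dies out) or `max_steps` is
#' reached, recording global metrics every `record_every` steps.
#'
#' @inheritParams abm_step
#' @param max_steps Step cap.
#' @param record_every Recording stride for the metric trajectory.
#' @param check_capacity Assert the per-patch capacity invariant after
#'   every step (used in tests).
#' @return An object of class `"abm_run"`: `winner`, `steps`, `trajectory`
#'   (tibble of step, counts, per-genotype diversity, assortment, disaster
#'   flag/target), `final_world` and `params`.  Use [tidy()] / [glance()] /
#'   [autoplot()].
#' @examples
#' w <- init_world(c(3, 3, 3), fill_fraction = 0.4, monoculture = "plus",
#'                 seed = 1)
#' run <- run_abm(w, max_steps = 50, seed = 2)
#' glance(run)
#' @export
run_abm <- function(world, disaster_prob = 0.01, kill_fraction = 0.99,
                    switch_prob = 0.1, migration_prob = 0.005,
                    pcd_prob = 0.025, neighbors = 6, max_steps = 20000,
                    record_every = 1, check_capacity = FALSE, seed = NULL) {
  world <- as_world(world)
  check_prob(disaster_prob, "disaster_prob")
  check_prob(kill_fraction, "kill_fraction")
  check_prob(switch_prob, "switch_prob")
  check_prob(migration_prob, "migration_prob")
  check_prob(pcd_prob, "pcd_prob")
  check_count(max_steps, "max_steps", min = 1)
  check_count(record_every, "record_every", min = 1)
  neighbors <- match.arg(as.character(neighbors), c("6", "26"))
  res <- run_seeded(seed, abm_run_cpp(
    world$counts, world$dims, world$capacity, disaster_prob, kill_fraction,
    switch_prob, migration_prob, pcd_prob, neighbors == "26",
    as.integer(max_steps), as.integer(record_every), check_capacity))
  tr <- res$trajectory
  traj <- tibble::tibble(
    step = tr$step, a_plus = tr$a_plus, b_plus = tr$b_plus,
    a_minus = tr$a_minus, b_minus = tr$b_minus,
    total = tr$a_plus + tr$b_plus + tr$a_minus + tr$b_minus,
    diversity_plus = tr$diversity_plus,
    diversity_minus = tr$diversity_minus,
    assortment = tr$assortment,
    disaster = tr$disaster == 1L,
    target = decode_target(tr$target))
  counts <- res$counts
  colnames(counts) <- colnames(world$counts)
  structure(list(
    winner = decode_winner(res$winner),
    steps = res$steps,
    trajectory = traj,
    final_world = structure(list(counts = counts, dims = world$dims,
                                 capacity = world$capacity),
                            class = "pcd_world"),
    params = list(disaster_prob = disaster_prob,
                  kill_fraction = kill_fraction, switch_prob = switch_prob,
                  migration_prob = migration_prob, pcd_prob = pcd_prob,
                  neighbors = as.integer(neighbors), max_steps = max_steps,
                  record_every = record_every),
    seed = seed), class = "abm_run")
}

#' @export
print.abm_run <- function(x, ...) {
  cat("<abm_run>  outcome:", x$winner, " steps:", x$steps, "\n")
  invisible(x)
}

#' Sweep ABM competitions over disaster and migration grids
#'
#' Runs `reps` competitions between a PCD+ and a PCD- strain for every
#' combination of disaster and migration probability, and reports the PCD+
#' win fraction (extinction plus timeout-majority wins over competitions
#' where at least one genotype survived and no tie), the across-run mean of
#' the time-averaged assortment, the mean steps to resolution, and the
#' number of runs still unresolved at the step cap.
#'
#' @inheritParams run_abm
#' @param disaster_probs,migration_probs Parameter vectors to cross.
#' @param reps Replicates per combination.
#' @param dims,capacity,fill_fraction World geometry (see [init_world()]);
#'   a fresh 50:50 world is drawn per replicate.
#' @param seed Root seed; replicate streams are derived from it.
#' @return A tibble with one row per combination.
#' @examples
#' competition_sweep(c(0.005, 0.02), 0.005, reps = 2, dims = c(3, 3, 3),
#'                   max_steps = 60, seed = 1)
#' @export
competition_sweep <- function(disaster_probs, migration_probs, reps = 100,
                              dims = c(10, 10, 10), capacity = 10,
                              fill_fraction = 0.5, kill_fraction = 0.99,
                              switch_prob = 0.1, pcd_prob = 0.025,
                              neighbors = 6, max_steps = 20000,
                              seed = NULL) {
  check_count(reps, "reps", min = 1)
  grid <- tidyr::crossing(disaster_prob = disaster_probs,
                          migration_prob = migration_probs)
  rows <- purrr::imap(purrr::transpose(as.list(grid)), function(g, idx) {
    winners <- integer(reps)
    mean_r <- numeric(reps)
    steps <- integer(reps)
    for (i in seq_len(reps)) {
      sd_i <- if (is.null(seed)) NULL else child_seed(seed, idx, i)
      run <- run_seeded(sd_i, {
        w <- init_world(dims, capacity, fill_fraction, prop_plus = 0.5)
        run_abm(w, disaster_prob = g$disaster_prob,
                kill_fraction = kill_fraction, switch_prob = switch_prob,
                migration_prob = g$migration_prob, pcd_prob = pcd_prob,
                neighbors = neighbors, max_steps = max_steps,
                record_every = 10)
      })
      winners[i] <- match(run$winner, winner_labels)
      mean_r[i] <- mean(run$trajectory$assortment, na.rm = TRUE)
      steps[i] <- run$steps
    }
    s <- summarise_winners(winners, reps)
    s$mean_assortment <- mean(mean_r, na.rm = TRUE)
    s$mean_steps <- mean(steps)
    s$unresolved <- sum(winners >= 4L)
    s
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(rows))
}
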