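# 2D spatially-explicit model: assortment is emergent and locally measured.
# A lattice is an integer matrix of site codes; the Moore (8-site)
# neighbourhood with non-periodic edges is used throughout.

#' Site codes used by the lattice model
#'
#' Integer codes of the five site states: `empty = 0`, `a_plus = 1`
#' (PCD+ phenotype A), `b_plus = 2`, `a_minus = 3`, `b_minus = 4`.
#'
#' @return A named integer vector.
#' @examples
#' lattice_codes()
#' @export
lattice_codes <- function() {
  c(empty = 0L, a_plus = 1L, b_plus = 2L, a_minus = 3L, b_minus = 4L)
}

as_lattice <- function(lattice) {
  if (!is.matrix(lattice) || !is.numeric(lattice) ||
      any(!(lattice %in% 0:4))) {
    stop("`lattice` must be an integer matrix of site codes 0..4 ",
         "(see `lattice_codes()`)", call. = FALSE)
  }
  storage.mode(lattice) <- "integer"
  lattice
}

lattice_count_row <- function(lattice) {
  tibble::tibble(
    a_plus = sum(lattice == 1L), b_plus = sum(lattice == 2L),
    a_minus = sum(lattice == 3L), b_minus = sum(lattice == 4L),
    empty = sum(lattice == 0L))
}

#' Build an initial lattice with a target mean assortment
#'
#' Fills the grid with equal numbers of PCD+ and PCD- cells (within one when
#' the site count is odd), assigns phenotypes A/B with probability 0.5, and
#' then performs random same-phenotype genotype swaps, accepting a swap
#' whenever it moves the measured mean assortment towards `target_r`.  High
#' targets start from two half-grid genotype blocks, others from a uniform
#' random mix.  For a 50:50 genotype mixture the attainable range is roughly
#' `[0.5, 0.99]`; an unattainable target fails after the proposal cap with
#' an error naming the assortment actually achieved.
#'
#' @param target_r Target mean assortment of the PCD+ cells.
#' @param rows,cols Lattice dimensions.
#' @param max_iter Proposal cap for the swap process.
#' @param seed Optional integer seed.
#' @return An integer lattice matrix (see [lattice_codes()]) whose measured
#'   mean assortment is within 0.02 of `target_r`.
#' @examples
#' g <- init_lattice(0.9, rows = 40, cols = 40, seed = 1)
#' measure_assortment(g)$mean_r
#' @export
init_lattice <- function(target_r, rows = 100, cols = 100,
                         max_iter = 500000, seed = NULL) {
  check_prob(target_r, "target_r")
  check_count(rows, "rows", min = 2)
  check_count(cols, "cols", min = 2)
  res <- run_seeded(seed, lat_init_cpp(target_r, as.integer(rows),
                                       as.integer(cols),
                                       as.integer(max_iter), 0.01))
  if (abs(res$achieved_r - target_r) > 0.02) {
    stop(sprintf(paste0("could not reach target assortment %.3f on a ",
                        "%d x %d lattice: achieved %.3f after %d proposals"),
                 target_r, rows, cols, res$achieved_r, res$iterations),
         call. = FALSE)
  }
  res$grid
}

#' Measure local assortment on a lattice
#'
#' Every PCD+ cell gets its own assortment: the fraction of its living
#' Moore neighbours that share its genotype.  Cells with no living
#' neighbour are excluded.  The summary is the arithmetic mean over the
#' included PCD+ cells; with no qualifying cell the mean is `NA` and the
#' summary is flagged undefined.
#'
#' @param lattice Integer lattice matrix.
#' @param per_cell Also return the per-cell values and their positions.
#' @return A list of class `"assortment_summary"` with `mean_r`,
#'   `n_cells`, `undefined`, and (if requested) a `per_cell` tibble with
#'   columns `row`, `col`, `r`.
#' @examples
#' g <- matrix(c(3, 3, 3, 3, 1, 3, 3, 3, 3), 3, 3)
#' measure_assortment(g)$mean_r  # single PCD+ cell, all neighbours PCD-
#' @export
measure_assortment <- function(lattice, per_cell = FALSE) {
  g <- as_lattice(lattice)
  res <- lat_measure_r_cpp(g, per_cell)
  out <- list(mean_r = res$mean_r, n_cells = res$n_cells,
              undefined = res$n_cells == 0L)
  if (per_cell) {
    out$per_cell <- tibble::tibble(row = res$row, col = res$col,
                                   r = res$r_values)
  }
  structure(out, class = "assortment_summary")
}

#' @export
print.assortment_summary <- function(x, ...) {
  if (x$undefined) {
    cat("<assortment_summary>  undefined (no PCD+ cell with living",
        "neighbours)\n")
  } else {
    cat(sprintf("<assortment_summary>  mean r = %.4f over %d PCD+ cells\n",
                x$mean_r, x$n_cells))
  }
  invisible(x)
}

#' Repopulate a lattice from living neighbours
#'
#' Iterative passes: within a pass, every empty site with at least one
#' neighbour that was alive at the start of the pass is filled (in random
#' order) by an offspring of a uniformly chosen such neighbour; offspring
#' inherit the parent's genotype and switch phenotype with that genotype's
#' switch probability, and become available as parents in the next pass.
#' Passes repeat until the lattice is full.
#'
#' @inheritParams measure_assortment
#' @param p_plus,p_minus Switch probabilities of the two genotypes.
#' @param seed Optional integer seed.
#' @return The filled lattice.
#' @examples
#' g <- matrix(0L, 3, 3); g[1, 1] <- 1L
#' repopulate_lattice(g, p_plus = 0, seed = 1)
#' @export
repopulate_lattice <- function(lattice, p_plus, p_minus = p_plus,
                               seed = NULL) {
  g <- as_lattice(lattice)
  if (all(g == 0L)) {
    stop("cannot repopulate a lattice with no living cells", call. = FALSE)
  }
  check_prob(p_plus, "p_plus")
  check_prob(p_minus, "p_minus")
  run_seeded(seed, lat_repopulate_cpp(g, p_plus, p_minus))
}

#' One lattice round
#'
#' With probability `disaster_prob` a uniformly chosen phenotype is
#' annihilated lattice-wide; each surviving PCD+ cell then dies with
#' probability `pcd_prob` (deaths resolved simultaneously); finally the
#' lattice is refilled by [repopulate_lattice()].  The round log records
#' the disaster flag and target, whether the target switched relative to
#' `previous_target`, the mean assortment before and after the round, and
#' the post-round counts.
#'
#' @inheritParams repopulate_lattice
#' @param pcd_prob Per-round PCD probability.
#' @param disaster_prob Per-round disaster probability.
#' @param previous_target Target of the most recent disaster (`"A"`, `"B"`)
#'   or `NA` if none has happened yet.
#' @return A list with `lattice` (the new grid, or `NULL` when the round
#'   annihilated every living cell, flagged by `extinct_all`) and `log`, a
#'   one-row tibble.
#' @examples
#' g <- init_lattice(0.5, rows = 20, cols = 20, seed = 1)
#' out <- lattice_round(g, pcd_prob = 0.05, disaster_prob = 0,
#'                      p_plus = 0.1, seed = 2)
#' out$log
#' @export
lattice_round <- function(lattice, pcd_prob, disaster_prob, p_plus,
                          p_minus = p_plus, previous_target = NA,
                          seed = NULL) {
  g <- as_lattice(lattice)
  check_prob(pcd_prob, "pcd_prob")
  check_prob(disaster_prob, "disaster_prob")
  check_prob(p_plus, "p_plus")
  check_prob(p_minus, "p_minus")
  prev <- if (is.na(previous_target)) -1L
          else if (match.arg(previous_target, c("A", "B")) == "A") 0L else 1L
  res <- run_seeded(seed, lat_round_cpp(g, pcd_prob, disaster_prob, p_plus,
                                        p_minus, prev))
  log <- tibble::tibble(
    disaster = res$disaster,
    target = decode_target(res$target),
    switched_target = if (is.na(res$switched)) NA else res$switched == 1L,
    mean_r_before = res$mean_r_before,
    mean_r = res$mean_r_after,
    delta_r = res$mean_r_after - res$mean_r_before,
    a_plus = res$counts[1], b_plus = res$counts[2],
    a_minus = res$counts[3], b_minus = res$counts[4],
    extinct_all = res$extinct_all)
  list(lattice = if (res$extinct_all) NULL else res$grid, log = log)
}

#' Run one lattice competition
#'
#' Initialises a lattice at `target_r` (unless `init` is given) and runs
#' rounds until one genotype goes extinct or `max_rounds` have passed
#' (majority rule at the cap).  The full per-round trajectory of counts and
#' mean assortment is returned.
#'
#' @inheritParams lattice_round
#' @param target_r Target mean assortment of the initial configuration.
#' @param switch_prob Switch probability of both genotypes.
#' @param rows,cols Lattice dimensions.
#' @param max_rounds Round cap.
#' @param init Optional pre-built lattice (overrides `target_r`).
#' @param seed Optional integer seed (covers initialisation and dynamics).
#' @return An object of class `"lattice_competition"`: `winner`, `rounds`,
#'   `trajectory` (tibble with per-round counts, `mean_r_before`, `mean_r`,
#'   `delta_r`, `disaster`, `target`, `switched_target`), `final_lattice`
#'   and `params`.  Use [tidy()] / [glance()] / [autoplot()].
#' @examples
#' lc <- run_lattice_competition(target_r = 0.5, rows = 20, cols = 20,
#'                               max_rounds = 50, seed = 1)
#' glance(lc)
#' @export
run_lattice_competition <- function(target_r = 0.5, pcd_prob = 0.05,
                                    disaster_prob = 0.05, switch_prob = 0.1,
                                    rows = 100, cols = 100,
                                    max_rounds = 100000, init = NULL,
                                    seed = NULL) {
  check_prob(pcd_prob, "pcd_prob")
  check_prob(disaster_prob, "disaster_prob")
  check_prob(switch_prob, "switch_prob")
  check_count(max_rounds, "max_rounds", min = 1)
  res <- run_seeded(seed, {
    g <- if (is.null(init)) {
      init_lattice(target_r, rows = rows, cols = cols)
    } else {
      as_lattice(init)
    }
    lat_run_cpp(g, pcd_prob, disaster_prob, switch_prob, switch_prob,
                as.integer(max_rounds))
  })
  tr <- res$trajectory
  traj <- tibble::tibble(
    round = tr$round, a_plus = tr$a_plus, b_plus = tr$b_plus,
    a_minus = tr$a_minus, b_minus = tr$b_minus,
    disaster = tr$disaster == 1L, target = decode_target(tr$target),
    switched_target = ifelse(is.na(tr$switched), NA, tr$switched == 1L),
    mean_r_before = tr$mean_r_before, mean_r = tr$mean_r_after,
    delta_r = tr$mean_r_after - tr$mean_r_before)
  structure(list(
    winner = decode_winner(res$winner),
    rounds = res$rounds,
    trajectory = traj,
    final_lattice = res$grid,
    params = list(target_r = if (is.null(init)) target_r else NA,
                  pcd_prob = pcd_prob, disaster_prob = disaster_prob,
                  switch_prob = switch_prob, rows = nrow(res$grid),
                  cols = ncol(res$grid), max_rounds = max_rounds),
    seed = seed), class = "lattice_competition")
}

#' @export
print.lattice_competition <- function(x, ...) {
  cat("<lattice_competition>  winner:", x$winner, " rounds:", x$rounds,
      "\n")
  last <- x$trajectory[nrow(x$trajectory), ]
  cat(sprintf("  final counts: A+ %d  B+ %d  A- %d  B- %d   mean r %.3f\n",
              last$a_plus, last$b_plus, last$a_minus, last$b_minus,
              last$mean_r))
  invisible(x)
}

#' Conditional per-round assortment changes
#'
#' Classifies every logged round as disaster-free, a disaster whose target
#' differs from the previous disaster's target, or a repeat-target disaster,
#' and reports the mean per-round change in mean assortment for each class
#' with its standard error.  The first disaster of a run has no previous
#' target and is excluded from the two disaster classes.
#'
#' @param logs A tibble of pooled round logs with columns `disaster`
#'   (logical), `switched_target` (logical, `NA` allowed) and `delta_r`,
#'   e.g. row-bound [tidy()] outputs of several
#'   [run_lattice_competition()] objects.
#' @return A tibble with one row per class: `n`, `mean_delta_r`, `se`.
#'   An empty class has `n = 0` and `NA` statistics.
#' @examples
#' logs <- tibble::tibble(disaster = c(FALSE, TRUE, TRUE),
#'                        switched_target = c(NA, NA, TRUE),
#'                        delta_r = c(-0.001, 0.02, 0.08))
#' delta_r_statistics(logs)
#' @export
delta_r_statistics <- function(logs) {
  need <- c("disaster", "switched_target", "delta_r")
  if (!all(need %in% names(logs))) {
    stop("`logs` must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  logs <- dplyr::filter(logs, !is.na(.data$delta_r))
  cls <- dplyr::case_when(
    !logs$disaster ~ "no_disaster",
    logs$disaster & !is.na(logs$switched_target) & logs$switched_target ~
      "disaster_switched",
    logs$disaster & !is.na(logs$switched_target) ~ "disaster_repeat",
    TRUE ~ NA_character_)
  kept <- tibble::tibble(class = cls, delta_r = logs$delta_r)
  kept <- dplyr::filter(kept, !is.na(.data$class))
  out <- dplyr::summarise(
    dplyr::group_by(kept, .data$class),
    n = dplyr::n(),
    mean_delta_r = mean(.data$delta_r),
    se = stats::sd(.data$delta_r) / sqrt(dplyr::n()),
    .groups = "drop")
  all_classes <- tibble::tibble(class = c("no_disaster",
                                          "disaster_switched",
                                          "disaster_repeat"))
  out <- dplyr::left_join(all_classes, out, by = "class")
  dplyr::mutate(out, n = dplyr::coalesce(.data$n, 0L))
}

#' Plain-text snapshot of a lattice
#'
#' One character per site (`.` empty, `a`/`b` PCD+ phenotypes A/B,
#' `A`/`B` PCD-), one string per row: a cheap grid dump for visual
#' inspection, logs and fixtures.  `write_lattice()` writes it to a file;
#' the format round-trips through `read_lattice()`.
#'
#' @inheritParams measure_assortment
#' @param path File path.
#' @return `format_lattice()`: a character vector of row strings.
#'   `read_lattice()`: an integer lattice matrix.
#' @examples
#' g <- init_lattice(0.9, rows = 6, cols = 6, seed = 1)
#' cat(format_lattice(g), sep = "\n")
#' @export
format_lattice <- function(lattice) {
  g <- as_lattice(lattice)
  chars <- c(".", "a", "b", "A", "B")
  apply(g, 1, function(row) paste(chars[row + 1L], collapse = ""))
}

#' @rdname format_lattice
#' @export
write_lattice <- function(lattice, path) {
  writeLines(format_lattice(lattice), path)
  invisible(path)
}

#' @rdname format_lattice
#' @export
read_lattice <- function(path) {
  lines <- readLines(path)
  chars <- c(".", "a", "b", "A", "B")
  m <- t(vapply(strsplit(lines, ""), function(x)
    match(x, chars) - 1L, integer(nchar(lines[1]))))
  storage.mode(m) <- "integer"
  as_lattice(m)
}
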