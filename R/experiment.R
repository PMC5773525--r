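# Reproducible experiment driver: config validation, dispatch, and
# delimited-text output with a commented metadata header.  Identical
# (config, seed) pairs produce byte-identical files.

config_keys <- list(
  analytic = c("quantity", "switch_prob", "pcd_prob", "assortment", "m",
               "rounds"),
  wellmixed = c("mode", "switch_prob", "p_minus", "pcd_prob", "assortment",
                "disaster_prob", "capacity", "kill_fraction", "max_rounds",
                "reps"),
  lattice = c("mode", "target_r", "pcd_prob", "disaster_prob",
              "switch_prob", "rows", "cols", "max_rounds", "reps"),
  abm = c("mode", "dims", "capacity", "fill_fraction", "disaster_prob",
          "kill_fraction", "switch_prob", "migration_prob", "pcd_prob",
          "neighbors", "max_steps", "record_every", "reps"))

#' Run a configured experiment
#'
#' Dispatches a configuration (a named list, or the path of a YAML file) to
#' one of the four models and writes the result tables as tab-separated
#' text with a commented metadata header into `outdir`, together with the
#' resolved configuration.  The same configuration and seed always produce
#' byte-identical files.
#'
#' Common keys: `model` (`"analytic"`, `"wellmixed"`, `"lattice"`,
#' `"abm"`), `seed`, `outdir`.  Model blocks take the corresponding
#' function arguments (`mode` is `"run"` for a single trajectory or
#' `"sweep"` for a win-fraction table).  Unknown keys are rejected.
#'
#' @param config Named list or path to a YAML file.
#' @param outdir Output directory (overrides `config$outdir`).
#' @param seed Root seed (overrides `config$seed`).
#' @return Invisibly, a list with `files` (paths written) and `result`
#'   (the main result tibble).
#' @examples
#' dir <- tempfile()
#' run_experiment(list(model = "analytic", quantity = "cost_factor",
#'                     pcd_prob = 0.1, assortment = c(0.5, 1), rounds = 10),
#'                outdir = dir)
#' @export
run_experiment <- function(config, outdir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$model)) {
    stop("`config` must be a named list (or YAML file) with a `model` key",
         call. = FALSE)
  }
  model <- match.arg(config$model, names(config_keys))
  outdir <- outdir %||% config$outdir %||%
    stop("no output directory given (`outdir`)", call. = FALSE)
  seed <- seed %||% config$seed
  allowed <- c("model", "seed", "outdir", config_keys[[model]])
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s) for model '", model, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config[setdiff(names(config), c("model", "seed", "outdir"))]
  out <- switch(model,
    analytic = experiment_analytic(cfg),
    wellmixed = experiment_wellmixed(cfg, seed),
    lattice = experiment_lattice(cfg, seed),
    abm = experiment_abm(cfg, seed))
  resolved <- c(list(model = model, seed = seed), cfg)
  yaml::write_yaml(resolved, file.path(outdir, "config.yml"))
  files <- file.path(outdir, "config.yml")
  for (nm in names(out)) {
    path <- file.path(outdir, paste0(nm, ".tsv"))
    write_result_table(out[[nm]], path, resolved)
    files <- c(files, path)
  }
  invisible(list(files = files, result = out[[1]]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_result_table <- function(tbl, path, resolved) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# pcdbet ", as.character(utils::packageVersion("pcdbet"))),
    paste0("# seed: ", resolved$seed %||% "none"),
    paste0("# config: ", paste(names(resolved), vapply(resolved, function(v)
      paste(format(v), collapse = ","), character(1)),
      sep = "=", collapse = " "))), con)
  write.table(as.data.frame(tbl), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

call_with <- function(fn, cfg, extra = list()) {
  args <- c(cfg, extra)
  do.call(fn, args[names(args) %in% names(formals(fn))])
}

experiment_analytic <- function(cfg) {
  list(analytic = call_with(analytic_grid, cfg))
}

experiment_wellmixed <- function(cfg, seed) {
  mode <- match.arg(cfg$mode %||% "sweep", c("run", "sweep"))
  cfg$mode <- NULL
  if (mode == "run") {
    cmp <- call_with(run_competition,
                     stats::setNames(cfg, sub("^switch_prob$", "p_plus",
                                              names(cfg))),
                     list(seed = seed))
    list(summary = glance(cmp), trajectory = tidy(cmp))
  } else {
    list(sweep = call_with(win_fraction_sweep, cfg, list(seed = seed)))
  }
}

experiment_lattice <- function(cfg, seed) {
  mode <- match.arg(cfg$mode %||% "run", c("run", "sweep"))
  cfg$mode <- NULL
  if (mode == "run") {
    run <- call_with(run_lattice_competition, cfg, list(seed = seed))
    list(summary = glance(run), trajectory = tidy(run))
  } else {
    reps <- cfg$reps %||% 10
    cfg$reps <- NULL
    runs <- purrr::map(seq_len(reps), function(i) {
      call_with(run_lattice_competition, cfg,
                list(seed = if (is.null(seed)) NULL
                     else child_seed(seed, 1, i)))
    })
    summary <- dplyr::bind_cols(
      tibble::tibble(rep = seq_len(reps)),
      dplyr::bind_rows(purrr::map(runs, glance)))
    pooled <- dplyr::bind_rows(purrr::map(runs, tidy), .id = "rep")
    list(summary = summary, delta_r = delta_r_statistics(pooled))
  }
}

experiment_abm <- function(cfg, seed) {
  mode <- match.arg(cfg$mode %||% "run", c("run", "sweep"))
  cfg$mode <- NULL
  if (mode == "run") {
    run <- run_seeded(seed, {
      w <- call_with(init_world, cfg)
      call_with(run_abm, cfg, list(world = w))
    })
    list(summary = glance(run), trajectory = tidy(run))
  } else {
    cfg$disaster_probs <- cfg$disaster_prob %||% 0.01
    cfg$migration_probs <- cfg$migration_prob %||% 0.005
    cfg$disaster_prob <- NULL
    cfg$migration_prob <- NULL
    list(sweep = call_with(competition_sweep, cfg, list(seed = seed)))
  }
}

#' Reduced-scale acceptance report
#'
#' Re-runs the package's headline checks at a reduced scale and prints
#' observed values against the expected direction or value: the exact
#' closed-form checks for the analytic layer, and directional Monte-Carlo
#' checks for the three stochastic models.  Intended as a quick smoke
#' audit; the test suite performs the full-scale versions.
#'
#' @param suite One of `"analytic"`, `"wellmixed"`, `"lattice"`, `"abm"`,
#'   `"all"`.
#' @param seed Root seed for the stochastic suites.
#' @return A tibble with columns `check`, `observed`, `criterion`, `pass`,
#'   invisibly; printed as a side effect.
#' @examples
#' acceptance_report("analytic")
#' @export
acceptance_report <- function(suite = c("analytic", "wellmixed", "lattice",
                                        "abm", "all"), seed = 1) {
  suite <- match.arg(suite)
  rows <- list()
  add <- function(check, observed, criterion, pass) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      check = check, observed = observed, criterion = criterion,
      pass = pass)
  }
  if (suite %in% c("analytic", "all")) {
    cf <- cost_factor(c(0, 0.1, 0.5, 1), 1, 10)
    add("cost factor at perfect assortment", max(abs(cf - 1)),
        "== 0", all(cf == 1))
    l10 <- benefit_cost_ratio(1e-6, 0.09, 11, 0.5, log10 = TRUE)
    add("log10 benefit:cost, p=1e-6 r=0.5 c=0.09 m=11", l10, "> 6",
        l10 > 6)
    tt <- time_to_stationary_diversity(1e-3, 0.005)
    add("generations to stationary diversity at p=1e-3", tt, "> 1000",
        tt > 1000)
  }
  if (suite %in% c("wellmixed", "all")) {
    sw <- win_fraction_sweep(switch_prob = 0.1, pcd_prob = 0.05,
                             assortment = 0.9, disaster_prob = 0.1,
                             reps = 50, capacity = 2500, max_rounds = 2500,
                             seed = seed)
    add("PCD+ win fraction, structured (r=0.9, d=0.1)", sw$win_fraction,
        "> 0.5", sw$win_fraction > 0.5)
  }
  if (suite %in% c("lattice", "all")) {
    runs <- purrr::map(1:6, function(i) run_lattice_competition(
      target_r = 0.75, rows = 50, cols = 50, max_rounds = 600,
      seed = child_seed(seed, 1, i)))
    pooled <- dplyr::bind_rows(purrr::map(runs, tidy))
    st <- delta_r_statistics(pooled)
    nd <- st$mean_delta_r[st$class == "no_disaster"]
    sw <- st$mean_delta_r[st$class == "disaster_switched"]
    add("mean delta r, no-disaster rounds", nd, "< 0", isTRUE(nd < 0))
    add("mean delta r, target-switching disasters", sw, "> 0",
        isTRUE(sw > 0))
  }
  if (suite %in% c("abm", "all")) {
    runs <- purrr::map(c("plus", "minus"), function(g) {
      w <- init_world(c(5, 5, 5), fill_fraction = 0.5, monoculture = g,
                      seed = child_seed(seed, 2, 1))
      glance(run_abm(w, pcd_prob = if (g == "plus") 0.025 else 0,
                     max_steps = 600, seed = child_seed(seed, 2, 2)))
    })
    add("monoculture mean log population, PCD+ minus PCD-",
        runs[[1]]$mean_log_pop - runs[[2]]$mean_log_pop, "> 0",
        runs[[1]]$mean_log_pop > runs[[2]]$mean_log_pop)
    add("monoculture CV of population, PCD+ minus PCD-",
        runs[[1]]$cv_pop - runs[[2]]$cv_pop, "< 0",
        runs[[1]]$cv_pop < runs[[2]]$cv_pop)
  }
  out <- dplyr::bind_rows(rows)
  print(out, n = Inf)
  invisible(out)
}
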