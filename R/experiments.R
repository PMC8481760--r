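#' Experiment specification
#'
#' Describes one reproducible experiment: which designs to run, the
#' sample-size and threshold grids, the number of Monte Carlo replicates, and
#' the master seed. Grid defaults bracket the sample sizes and thresholds the
#' operating-characteristic analyses are reported at.
#'
#' @param experiment `"BASE_CASE"`, `"SWEEP_N"` or `"SWEEP_THRESHOLD"`.
#' @param designs Subset of `c("SMART", "RCT")`.
#' @param n_grid Sample sizes for sweeps (default `c(20, 50, 100, 300, 500,
#'   1700)`; the threshold sweep defaults to `c(20, 50, 100, 300)`).
#' @param delta_grid Response thresholds for the sensitivity sweep (default
#'   `seq(-1, 2, by = 0.1)`).
#' @param b Monte Carlo replicates per grid point (>= 2).
#' @param master_seed Integer master seed; grid-point sub-seeds are spawned
#'   from it, with the same sub-seed shared by both designs at a grid point
#'   (paired populations).
#' @param output_dir Optional directory for CSV output; `NULL` returns tables
#'   only.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(experiment = c("BASE_CASE", "SWEEP_N", "SWEEP_THRESHOLD"),
                            designs = c("SMART", "RCT"),
                            n_grid = NULL,
                            delta_grid = seq(-1, 2, by = 0.1),
                            b = 10000, master_seed = 1L, output_dir = NULL) {
  experiment <- match.arg(experiment)
  designs <- match.arg(designs, c("SMART", "RCT"), several.ok = TRUE)
  if (is.null(n_grid))
    n_grid <- if (experiment == "SWEEP_THRESHOLD") c(20, 50, 100, 300)
              else c(20, 50, 100, 300, 500, 1700)
  if (!length(n_grid) || !length(delta_grid)) stop("grids must be non-empty")
  if (!is.numeric(b) || b < 2) stop("b must be at least 2")
  structure(list(experiment = experiment, designs = designs,
                 n_grid = as.integer(n_grid), delta_grid = delta_grid,
                 b = as.integer(b), master_seed = as.integer(master_seed),
                 output_dir = output_dir),
            class = "experiment_spec")
}

## deterministic sub-seed per grid point, shared across designs
.grid_seeds <- function(master_seed, n_points) {
  set.seed(master_seed)
  sample.int(2147483646L, n_points)
}

.maybe_write <- function(dt, spec, filename, meta) {
  if (!is.null(spec$output_dir)) {
    dir.create(spec$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_csv(dt, file.path(spec$output_dir, filename), meta)
  }
  dt
}

.meta_lines <- function(spec, gen, costs, extra = character()) {
  c(sprintf("experiment: %s", spec$experiment),
    sprintf("designs: %s", paste(spec$designs, collapse = ",")),
    sprintf("B: %d", spec$b),
    sprintf("master_seed: %d", spec$master_seed),
    sprintf("generative: %s", paste(sprintf("%s=%g", names(unclass(gen)),
                                            unlist(gen)), collapse = " ")),
    sprintf("costs: %s", paste(sprintf("%s=%g", names(unclass(costs)),
                                       unlist(costs)), collapse = " ")),
    extra)
}

#' Base-case operating characteristics (one table, both designs)
#'
#' Runs the base case (by default n = 100, delta = 0.5, B replicates) for each
#' requested design and emits a tidy long table: overall and per-AI Monte
#' Carlo mean and SD of final HbA1c, cost mean and SD, and per-AI selection
#' probabilities.
#'
#' @param spec An [experiment_spec()].
#' @param gen A [generative_params()] object.
#' @param costs A [cost_table()].
#' @param n,delta Base-case trial size and response threshold.
#' @param allocation Allocation scheme.
#' @return A `data.table` with columns `design`, `statistic`, `ai`, `value`
#'   (written to `<output_dir>/base_case.csv` when `output_dir` is set).
#' @export
run_base_case <- function(spec = experiment_spec("BASE_CASE"),
                          gen = generative_params(),
                          costs = default_cost_table(gen),
                          n = 100, delta = 0.5, allocation = "BALANCED") {
  seed <- .grid_seeds(spec$master_seed, 1L)
  rows <- lapply(spec$designs, function(d) {
    mc <- run_monte_carlo(d, n = n, B = spec$b, delta = delta, gen = gen,
                          costs = costs, master_seed = seed,
                          allocation = allocation)
    data.table(
      design = d,
      statistic = c("y_mean", "y_sd", "cost_mean", "cost_sd",
                    rep(c("y_mean", "y_sd", "p_opt"), each = 4L)),
      ai = c(NA_integer_, NA_integer_, NA_integer_, NA_integer_,
             rep(1:4, times = 3L)),
      value = c(mc$y_tilde_overall, mc$s_overall, mc$cost_mean, mc$cost_sd,
                mc$y_tilde_ai, mc$s_ai, mc$p_opt))
  })
  dt <- rbindlist(rows)
  .maybe_write(dt, spec, "base_case.csv",
               .meta_lines(spec, gen, costs,
                           c(sprintf("n: %d", n), sprintf("delta: %g", delta))))
}

#' Sample-size sweep of operating characteristics
#'
#' For each design and each `n` in `spec$n_grid`: overall Monte Carlo mean
#' and SD, cost mean, per-AI Monte Carlo SDs, and per-AI selection
#' probabilities.
#'
#' @inheritParams run_base_case
#' @return A long `data.table` (`design`, `n`, `statistic`, `ai`, `value`);
#'   written to `<output_dir>/sweep_n.csv` when `output_dir` is set.
#' @export
run_sweep_n <- function(spec = experiment_spec("SWEEP_N"),
                        gen = generative_params(),
                        costs = default_cost_table(gen),
                        delta = 0.5, allocation = "BALANCED") {
  seeds <- .grid_seeds(spec$master_seed, length(spec$n_grid))
  rows <- list()
  for (i in seq_along(spec$n_grid)) {
    n <- spec$n_grid[i]
    for (d in spec$designs) {
      mc <- run_monte_carlo(d, n = n, B = spec$b, delta = delta, gen = gen,
                            costs = costs, master_seed = seeds[i],
                            allocation = allocation)
      rows[[length(rows) + 1L]] <- data.table(
        design = d, n = n,
        statistic = c("y_mean", "y_sd", "cost_mean",
                      rep(c("y_sd", "p_opt"), each = 4L)),
        ai = c(NA_integer_, NA_integer_, NA_integer_, rep(1:4, times = 2L)),
        value = c(mc$y_tilde_overall, mc$s_overall, mc$cost_mean,
                  mc$s_ai, mc$p_opt))
    }
  }
  dt <- rbindlist(rows)
  .maybe_write(dt, spec, "sweep_n.csv",
               .meta_lines(spec, gen, costs, sprintf("delta: %g", delta)))
}

#' Response-threshold sensitivity sweep
#'
#' For each design, each `n` in `spec$n_grid` and each threshold in
#' `spec$delta_grid`: the Monte Carlo mean (and SD) of the overall final
#' HbA1c. Plotting `y_mean` against `delta` reproduces the U-shaped
#' sensitivity curve.
#'
#' @inheritParams run_base_case
#' @return A `data.table` (`design`, `n`, `delta`, `y_mean`, `y_sd`);
#'   written to `<output_dir>/sweep_threshold.csv` when `output_dir` is set.
#' @export
run_sweep_threshold <- function(spec = experiment_spec("SWEEP_THRESHOLD"),
                                gen = generative_params(),
                                costs = default_cost_table(gen),
                                allocation = "BALANCED") {
  grid <- expand.grid(delta = spec$delta_grid, n = spec$n_grid,
                      KEEP.OUT.ATTRS = FALSE)
  seeds <- .grid_seeds(spec$master_seed, nrow(grid))
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    for (d in spec$designs) {
      mc <- run_monte_carlo(d, n = grid$n[i], B = spec$b,
                            delta = grid$delta[i], gen = gen, costs = costs,
                            master_seed = seeds[i], allocation = allocation)
      rows[[length(rows) + 1L]] <- data.table(
        design = d, n = grid$n[i], delta = grid$delta[i],
        y_mean = mc$y_tilde_overall, y_sd = mc$s_overall)
    }
  }
  dt <- rbindlist(rows)
  .maybe_write(dt, spec, "sweep_threshold.csv", .meta_lines(spec, gen, costs))
}

#' Write a results table as CSV with a reproducibility header
#'
#' Plain RFC-4180 CSV preceded by `#`-prefixed metadata comment lines (all
#' parameters and the master seed), so identical configuration and seed yield
#' byte-identical files.
#'
#' @param dt A data frame / data.table.
#' @param path Output file path.
#' @param meta Character vector of metadata lines (written as `# <line>`).
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(dt, path, meta = character()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(meta))
    writeLines(paste0("# ", meta), con, sep = "\n")
  writeLines(paste(names(dt), collapse = ","), con, sep = "\n")
  df <- as.data.frame(dt)
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- format(df[[j]], digits = 15, trim = TRUE,
                                               scientific = FALSE)
  lines <- do.call(paste, c(df, sep = ","))
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Load an experiment configuration file
#'
#' Reads a YAML configuration with optional sections `generative`, `cost`,
#' `design`, and `experiment`; unspecified keys take the base-case defaults.
#' Unknown sections or keys are rejected with an error naming the offending
#' key; out-of-range values are rejected by the constructors.
#'
#' @param path Path to a YAML file. An empty (or missing-section) file yields
#'   the full base case.
#' @return A list with elements `gen` ([generative_params()]), `design`
#'   ([design_config()]), `costs` ([cost_table()]), `spec`
#'   ([experiment_spec()]).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration file must be a YAML mapping")
  known_sections <- c("generative", "cost", "design", "experiment")
  bad <- setdiff(names(raw), known_sections)
  if (length(bad)) stop("unknown configuration section: ", paste(bad, collapse = ", "))

  take <- function(section, allowed) {
    x <- raw[[section]]
    if (is.null(x)) return(list())
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop("unknown configuration key: ",
           paste(sprintf("%s$%s", section, bad), collapse = ", "))
    x
  }

  gen_args <- take("generative", names(formals(generative_params)))
  gen <- do.call(generative_params, gen_args)

  cost_args <- take("cost", names(formals(cost_table)))
  costs <- if (length(cost_args)) {
    defaults <- unclass(default_cost_table(gen))
    do.call(cost_table, modifyList(defaults, cost_args))
  } else default_cost_table(gen)

  design_args <- take("design", names(formals(design_config)))
  design <- do.call(design_config, design_args)

  spec_args <- take("experiment", names(formals(experiment_spec)))
  spec <- do.call(experiment_spec, spec_args)

  list(gen = gen, design = design, costs = costs, spec = spec)
}
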