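config_to_list <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  list(
    weights = config$policy$weights,
    n_actions = config$policy$n_actions,
    sigma_a = config$policy$sigma_a,
    sigma_s = config$env$sigma_s,
    alpha = config$env$alpha,
    beta = config$env$beta,
    sigma_r = config$env$sigma_r,
    lambda = config$lambda,
    memory_length = config$memory_length,
    n_steps = config$n_steps,
    seed = config$seed,
    reward_mean_form = config$reward_mean_form,
    reward_loss_form = config$reward_loss_form,
    reward_aggregate = config$reward_aggregate,
    update_start = config$update_start,
    optimizer = list(
      max_iterations = config$optimizer$max_iterations,
      x_tolerance = config$optimizer$x_tolerance,
      f_tolerance = config$optimizer$f_tolerance,
      restart_count = config$optimizer$restart_count,
      zero_delta = config$optimizer$zero_delta
    )
  )
}

config_keys <- c("weights", "n_actions", "sigma_a", "sigma_s", "alpha",
                 "beta", "sigma_r", "lambda", "memory_length", "n_steps",
                 "seed", "reward_mean_form", "reward_loss_form",
                 "reward_aggregate", "update_start", "optimizer")
optimizer_keys <- c("max_iterations", "x_tolerance", "f_tolerance",
                    "restart_count", "zero_delta")

config_from_list <- function(lst) {
  unknown <- setdiff(names(lst), config_keys)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  opt_lst <- lst$optimizer
  if (!is.null(opt_lst)) {
    unknown <- setdiff(names(opt_lst), optimizer_keys)
    if (length(unknown) > 0L) {
      stop("unknown optimizer key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  args <- list()
  for (key in setdiff(config_keys, "optimizer")) {
    v <- lst[[key]]
    if (!is.null(v) && length(v) > 0L) args[[key]] <- v
  }
  opt_args <- list()
  for (key in optimizer_keys) {
    v <- opt_lst[[key]]
    if (!is.null(v) && length(v) > 0L) opt_args[[key]] <- v
  }
  args$optimizer <- do.call(optimizer_options, opt_args)
  do.call(sim_config, args)
}

#' Load / write a simulation configuration (YAML or JSON)
#'
#' The file holds keys matching the [sim_config()] field names (plus a
#' nested `optimizer` block); missing keys take the standard defaults,
#' unknown keys raise a validation error naming the key.
#'
#' @param path file path; format chosen by extension (`.json` for JSON,
#'   anything else parsed as YAML).
#' @return `load_config` returns a validated `sim_config`; `write_config`
#'   returns `path` invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(lst)) lst <- list()
  config_from_list(lst)
}

#' @rdname load_config
#' @param config a [sim_config()] object.
#' @export
write_config <- function(config, path) {
  lst <- config_to_list(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

preset_names <- c("single_run", "memory_stoppage", "individuation",
                  "four_parameters", "multi_choice", "lambda_sweep")

#' Predefined experiment presets
#'
#' Each preset bundles the configurations and analysis of one study
#' condition:
#' \describe{
#'   \item{single_run}{one standard run (600 steps).}
#'   \item{memory_stoppage}{stoppage-time batches at memory lengths 20
#'     (600 steps) and 40 (1500 steps).}
#'   \item{individuation}{a batch of standard runs classified into the
#'     behavior taxonomy.}
#'   \item{four_parameters}{initial weights `(1.25, 0, 1.75, 0)` — two
#'     mixture components — classified for sandwich and allied behaviors.}
#'   \item{multi_choice}{batches at 3, 4, 5 and 6 actions (1500 steps),
#'     with the stoppage correlation/regression for 3 actions.}
#'   \item{lambda_sweep}{dominance direction and stoppage time across a
#'     lambda grid from 0 to 1.}
#' }
#'
#' @param name one of the preset names.
#' @param n_runs runs per condition (default 40).
#' @return a list of class `experiment_preset` with elements `name`,
#'   `configs` (named list of `sim_config`), `n_runs`, and `kind`.
#' @export
experiment_preset <- function(name = preset_names, n_runs = 40L) {
  name <- match.arg(name)
  n_runs <- as.integer(n_runs)
  configs <- switch(
    name,
    single_run = list(standard = sim_config()),
    memory_stoppage = list(
      delta20 = sim_config(memory_length = 20L, n_steps = 600L),
      delta40 = sim_config(memory_length = 40L, n_steps = 1500L)
    ),
    individuation = list(standard = sim_config()),
    four_parameters = list(
      four_params = sim_config(weights = c(1.25, 0, 1.75, 0))
    ),
    multi_choice = list(
      na3 = sim_config(n_actions = 3L, n_steps = 1500L),
      na4 = sim_config(n_actions = 4L, n_steps = 1500L),
      na5 = sim_config(n_actions = 5L, n_steps = 1500L),
      na6 = sim_config(n_actions = 6L, n_steps = 1500L)
    ),
    lambda_sweep = list(standard = sim_config())
  )
  structure(
    list(name = name, configs = configs,
         n_runs = if (name == "single_run") 1L else n_runs,
         lambda_grid = if (name == "lambda_sweep") {
           c(0, 0.2, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1)
         } else NULL),
    class = "experiment_preset"
  )
}

#' Run an experiment preset and write its artifacts
#'
#' Writes, under `out_dir`: trajectory CSVs (single_run), per-condition
#' batch-summary JSONs, the lambda-sweep CSV where applicable, and a
#' reproducibility manifest (resolved configs, seeds, package version).
#'
#' @param name preset name (see [experiment_preset()]).
#' @param out_dir output directory (created if needed).
#' @param seed_base first seed.
#' @param n_runs runs per condition.
#' @return invisibly, a named list of the computed results.
#' @export
run_preset <- function(name, out_dir, seed_base = 1L, n_runs = 40L) {
  preset <- experiment_preset(name, n_runs = n_runs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()

  if (preset$name == "single_run") {
    cfg <- preset$configs$standard
    cfg$seed <- as.integer(seed_base)
    traj <- run_simulation(cfg)
    write_trajectory(traj, file.path(out_dir, "trajectory.csv"))
    summ <- run_summary(traj)
    jsonlite::write_json(
      list(behavior = summ$behavior$label, detail = summ$behavior$detail,
           dominance = summ$dominance,
           stoppage = summ$stoppage),
      file.path(out_dir, "run_summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    results$trajectory <- traj
    results$summary <- summ
  } else if (preset$name == "lambda_sweep") {
    sweep <- lambda_sweep(preset$configs$standard, preset$lambda_grid,
                          n_runs = preset$n_runs, seed_base = seed_base)
    utils::write.csv(sweep, file.path(out_dir, "lambda_sweep.csv"),
                     row.names = FALSE)
    results$sweep <- sweep
  } else {
    offset <- 0L
    for (cond in names(preset$configs)) {
      b <- batch_run(preset$configs[[cond]], n_runs = preset$n_runs,
                     seed_base = seed_base + offset)
      offset <- offset + preset$n_runs
      jsonlite::write_json(
        batch_summary_to_list(b),
        file.path(out_dir, paste0("batch_", cond, ".json")),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
      results[[cond]] <- b
    }
  }

  manifest <- list(
    preset = preset$name,
    seed_base = as.integer(seed_base),
    n_runs = preset$n_runs,
    lambda_grid = preset$lambda_grid,
    configs = lapply(preset$configs, config_to_list),
    package_version = as.character(utils::packageVersion("choicesym"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(results)
}

batch_summary_to_list <- function(b) {
  list(
    n_runs = b$n_runs,
    seeds = b$seeds,
    n_censored_runs = b$n_censored_runs,
    mean_stoppage = b$mean_stoppage,
    sd_stoppage = b$sd_stoppage,
    behavior_freq = b$behavior_freq,
    pct_action2_positive = b$pct_action2_positive,
    labels = b$labels,
    dominance = b$dominance,
    first_stoppage = b$first_stoppage,
    second_stoppage = b$second_stoppage,
    regression = b$regression
  )
}
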