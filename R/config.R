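CONFIG_SCHEMA <- list(
  tree = c("generate", "file"),
  values = c("value_floor", "value_ceiling"),
  score = c("points_per_innovation", "diversity_weight"),
  policy = c("unique_attempt_budget", "totem_from_visible"),
  structure = c("variant", "group_size", "n_subgroups", "subgroup_size",
                "n_epochs", "retention"),
  experiment = c("n_replicates", "seed", "fresh_tree", "keep_event_logs"),
  output = c("dir")
)

TREE_GEN_KEYS <- c("n_base", "n_intermediate", "n_logs", "n_basic_logs",
                   "min_basic_log_closure", "max_inputs", "seed")

#' Read and validate a run configuration
#'
#' Configurations are declarative YAML (JSON, being a YAML subset, is
#' accepted too) with sections `tree` (either `generate:` parameters or a
#' `file:` path to a serialized tree), `values`, `score`, `policy`,
#' `structure`, `experiment` and `output`.  Every section and key is
#' optional — defaults mirror the original game's constants — but unknown
#' sections or keys are rejected so that typos fail loudly rather than
#' silently running the default.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return The validated configuration list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stopf("cannot parse config: %s",
                                            conditionMessage(e)))
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list (as parsed from YAML/JSON).
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stopf("config must be a mapping")
  unknown <- setdiff(names(cfg), names(CONFIG_SCHEMA))
  if (length(unknown) > 0) {
    stopf("unknown config section(s): %s", paste(unknown, collapse = ", "))
  }
  for (sec in names(cfg)) {
    keys <- names(cfg[[sec]])
    bad <- setdiff(keys, CONFIG_SCHEMA[[sec]])
    if (length(bad) > 0) {
      stopf("unknown key(s) in section '%s': %s", sec,
            paste(bad, collapse = ", "))
    }
  }
  if (!is.null(cfg$tree)) {
    if (!is.null(cfg$tree$generate) && !is.null(cfg$tree$file)) {
      stopf("config section 'tree' must give either 'generate' or 'file'")
    }
    badg <- setdiff(names(cfg$tree$generate), TREE_GEN_KEYS)
    if (length(badg) > 0) {
      stopf("unknown key(s) in tree.generate: %s",
            paste(badg, collapse = ", "))
    }
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Build an experiment configuration from a run configuration
#'
#' @param cfg A validated `run_config`.
#' @return An [experiment_config()].
#' @export
config_to_experiment <- function(cfg) {
  tree <- if (!is.null(cfg$tree$file)) {
    load_tree(cfg$tree$file)
  } else {
    do.call(tree_gen_params, cfg$tree$generate %||% list())
  }
  values <- do.call(log_value_params, cfg$values %||% list())
  score <- do.call(score_params, cfg$score %||% list())
  policy <- do.call(agent_policy, cfg$policy %||% list())
  struct <- do.call(population_structure, cfg$structure %||% list())
  exp_args <- cfg$experiment %||% list()
  do.call(experiment_config,
          c(list(tree = tree, structure = struct, policy = policy,
                 score = score, values = values), exp_args))
}

#' Run an experiment from a configuration file and write its outputs
#'
#' Runs the configured treatment and writes, into the output directory:
#' `results.csv` (the per-agent results table), `summary.json` (the
#' summary statistics) and `run_metadata.json` (the configuration echo
#' plus the master seed).  With `keep_event_logs` enabled,
#' `event_logs.csv` is written as well, one row per attempt.
#'
#' @param config A path to a config file or a validated `run_config`.
#' @param out_dir Output directory (overrides the config's `output.dir`;
#'   default `"totemsim_output"`).
#' @return Named character vector of the files written, invisibly.
#' @export
run_from_config <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else
    validate_run_config(config)
  out_dir <- out_dir %||% cfg$output$dir %||% "totemsim_output"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ec <- config_to_experiment(cfg)
  results <- run_experiment(ec)
  summary <- summarize_results(results, seed = derive_seed(ec$seed, -1))

  paths <- c(results = file.path(out_dir, "results.csv"),
             summary = file.path(out_dir, "summary.json"),
             metadata = file.path(out_dir, "run_metadata.json"))
  utils::write.csv(as.data.frame(results), paths[["results"]],
                   row.names = FALSE)
  jsonlite::write_json(unclass(summary), paths[["summary"]],
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(package = "totemsim",
         version = as.character(utils::packageVersion("totemsim")),
         master_seed = ec$seed,
         n_replicates = ec$n_replicates,
         config = unclass(cfg)),
    paths[["metadata"]], auto_unbox = TRUE, digits = NA, null = "null")
  if (ec$keep_event_logs) {
    ev <- attr(results, "event_logs")
    rows <- list()
    for (r in seq_along(ev)) {
      for (a in names(ev[[r]])) {
        lg <- ev[[r]][[a]]
        if (nrow(lg) > 0) {
          rows[[length(rows) + 1L]] <-
            cbind(data.frame(replicate = r, agent = a,
                             stringsAsFactors = FALSE), lg)
        }
      }
    }
    paths[["event_logs"]] <- file.path(out_dir, "event_logs.csv")
    utils::write.csv(do.call(rbind, rows), paths[["event_logs"]],
                     row.names = FALSE)
  }
  invisible(paths)
}
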