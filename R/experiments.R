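#' Configuration of a replicated bot experiment
#'
#' A treatment is a population structure plus an agent policy plus scoring
#' parameters, run for `n_replicates` independent replicates.  Replicate
#' `i` runs under the derived seed `derive_seed(seed, i)`, so the whole
#' experiment is reproducible from the master seed alone.  By default a
#' fresh tree (and fresh log values) is generated for every replicate, so
#' summaries average over realizations of the innovation landscape; pass
#' `fresh_tree = FALSE` to generate one tree up front and reuse it, or
#' supply a fixed `techtree` directly as `tree`.
#'
#' @param tree A [tree_gen_params()] object (tree generated per run) or a
#'   fixed `techtree`.
#' @param structure A [population_structure()].
#' @param policy An [agent_policy()].
#' @param score A [score_params()].
#' @param values A [log_value_params()] (ignored when a fixed tree already
#'   carries log values).
#' @param n_replicates Number of independent replicates (default 1000).
#' @param seed Master seed (default 1).
#' @param fresh_tree Regenerate the tree each replicate? Default `TRUE`;
#'   only meaningful when `tree` is a parameter set.
#' @param keep_event_logs Attach every agent's event log to the result
#'   (needed by [innovation_rate_table()]; default `FALSE`).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(tree = tree_gen_params(),
                              structure = population_structure(),
                              policy = agent_policy(),
                              score = score_params(),
                              values = log_value_params(),
                              n_replicates = 1000, seed = 1,
                              fresh_tree = TRUE, keep_event_logs = FALSE) {
  if (!inherits(tree, "tree_gen_params") && !inherits(tree, "techtree")) {
    stopf("tree must be tree_gen_params or a techtree")
  }
  stopifnot(inherits(structure, "population_structure"),
            inherits(policy, "agent_policy"),
            inherits(score, "score_params"),
            inherits(values, "log_value_params"))
  if (n_replicates < 1) stopf("n_replicates must be >= 1")
  structure(list(tree = tree, structure = structure, policy = policy,
                 score = score, values = values,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 fresh_tree = isTRUE(fresh_tree),
                 keep_event_logs = isTRUE(keep_event_logs)),
            class = "experiment_config")
}

# Logs available to an agent for its totem: its own produced logs, or, if
# the policy says so, also the logs its final-epoch neighbors produced.
agent_totem_logs <- function(states, agent, tree, schedule, policy) {
  own <- intersect(states[[agent]]$produced, tree_log_ids(tree))
  if (!policy$totem_from_visible) return(own)
  last <- length(schedule$epochs)
  nbrs <- schedule$epochs[[last]][[agent]]
  nb_logs <- unlist(lapply(nbrs, function(b)
    intersect(states[[b]]$produced, tree_log_ids(tree))),
    use.names = FALSE)
  unique(c(own, nb_logs))
}

#' Run a replicated experiment
#'
#' Executes `n_replicates` fully independent, seed-deterministic runs of
#' the configured treatment and collects one row per agent per replicate.
#'
#' @param config An [experiment_config()].
#' @return A data.frame of class `totem_results` with columns `replicate`,
#'   `agent`, `innovations`, `n_logs`, `best_totem_points`, `final_score`,
#'   `built_totem`.  When `keep_event_logs` is set the attribute
#'   `event_logs` holds, per replicate, each agent's event log.  The
#'   configuration is attached as attribute `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  fixed_tree <- NULL
  if (inherits(config$tree, "techtree")) {
    fixed_tree <- config$tree
  } else if (!config$fresh_tree) {
    fixed_tree <- withr::with_seed(derive_seed(config$seed, 0), {
      tr <- generate_tree_impl(config$tree)
      tr$log_values <- assign_log_values_impl_from_tree(tr, config$values)
      tr
    })
  }
  rows <- vector("list", config$n_replicates)
  ev_logs <- if (config$keep_event_logs)
    vector("list", config$n_replicates) else NULL
  for (r in seq_len(config$n_replicates)) {
    res <- withr::with_seed(derive_seed(config$seed, r), {
      if (is.null(fixed_tree)) {
        tree <- generate_tree_impl(config$tree)
        values <- assign_log_values_impl_from_tree(tree, config$values)
      } else {
        tree <- fixed_tree
        values <- tree$log_values %||%
          assign_log_values_impl_from_tree(tree, config$values)
      }
      schedule <- build_schedule_impl(config$structure)
      states <- run_population_impl(tree, config$structure, config$policy,
                                    schedule)
      list(tree = tree, values = values, schedule = schedule,
           states = states)
    })
    ags <- names(res$states)
    rep_rows <- lapply(ags, function(a) {
      st <- res$states[[a]]
      logs_avail <- agent_totem_logs(res$states, a, res$tree, res$schedule,
                                     config$policy)
      bt <- if (length(logs_avail) > 0)
        best_totem(res$values, logs_avail, config$score) else NULL
      pts <- if (is.null(bt)) 0 else bt$points
      data.frame(replicate = r, agent = a,
                 innovations = length(st$produced),
                 n_logs = length(intersect(st$produced,
                                           tree_log_ids(res$tree))),
                 best_totem_points = pts,
                 final_score = final_score(length(st$produced), pts,
                                           config$score),
                 built_totem = !is.null(bt),
                 stringsAsFactors = FALSE)
    })
    rows[[r]] <- do.call(rbind, rep_rows)
    if (config$keep_event_logs) {
      ev_logs[[r]] <- lapply(res$states, `[[`, "event_log")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- config
  if (config$keep_event_logs) attr(out, "event_logs") <- ev_logs
  class(out) <- c("totem_results", "data.frame")
  out
}

# assign_log_values without re-seeding (uses the current stream)
assign_log_values_impl_from_tree <- function(tree, params) {
  log_ids <- tree_log_ids(tree)
  if (length(log_ids) == 0L) return(stats::setNames(numeric(0), character(0)))
  cls <- all_closures(tree)
  comp <- vapply(log_ids, function(id) length(cls[[id]]), integer(1))
  assign_log_values_impl(log_ids, comp, params)
}

#' Summary statistics over an experiment's results
#'
#' Mean and standard deviation of the per-agent final scores, the
#' fraction of agents that built a totem, the mean innovation count, and
#' a percentile bootstrap confidence interval for the mean score
#' (resampling agents, 1,000 resamples by default).
#'
#' @param results A `totem_results` table (or any data.frame with
#'   `final_score`, `built_totem` and `innovations` columns).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `totem_summary`.
#' @export
summarize_results <- function(results, n_boot = 1000, conf = 0.95,
                              seed = NULL) {
  if (nrow(results) == 0L) stopf("cannot summarize an empty results table")
  x <- results$final_score
  ci <- with_seed_or_stream(seed, {
    boots <- vapply(seq_len(n_boot), function(i) {
      mean(x[sample.int(length(x), length(x), replace = TRUE)])
    }, numeric(1))
    stats::quantile(boots, probs = c((1 - conf) / 2, 1 - (1 - conf) / 2),
                    names = FALSE)
  })
  structure(list(mean_score = mean(x),
                 sd_score = stats::sd(x),
                 frac_totem = mean(results$built_totem),
                 ci_lower = ci[1], ci_upper = ci[2],
                 mean_innovations = mean(results$innovations),
                 n = nrow(results)),
            class = "totem_summary")
}

#' @export
print.totem_summary <- function(x, ...) {
  cat(sprintf("Final score: mean %.2f (s.d. %.2f), 95%% CI [%.2f, %.2f]\n",
              x$mean_score, x$sd_score, x$ci_lower, x$ci_upper))
  cat(sprintf("Mean innovations: %.2f; fraction building a totem: %.4f (n = %d)\n",
              x$mean_innovations, x$frac_totem, x$n))
  invisible(x)
}

#' Innovation-rate table: failures before each success
#'
#' For every innovation an agent discovered, reports its rank in the
#' agent's own record, the number of failed unique attempts since the
#' agent's previous success, and the number of possible combinations the
#' agent's pool offered at the moment of the success (the covariate that
#' controls for combinatorial explosion when analysing learning-to-learn
#' effects).
#'
#' @param x An `agent_state`, a list of them (as returned by
#'   [run_population()]), or a `totem_results` table built with
#'   `keep_event_logs = TRUE`.
#' @return data.frame with columns `replicate` (NA when not applicable),
#'   `agent`, `rank`, `failures_before`, `pool_size`,
#'   `possible_combinations`.
#' @export
innovation_rate_table <- function(x) {
  if (inherits(x, "agent_state")) {
    return(rate_rows(x$event_log, x$agent, NA_integer_))
  }
  if (inherits(x, "totem_results")) {
    ev <- attr(x, "event_logs")
    if (is.null(ev)) {
      stopf("results carry no event logs; run with keep_event_logs = TRUE")
    }
    out <- list()
    for (r in seq_along(ev)) {
      for (a in names(ev[[r]])) {
        out[[length(out) + 1L]] <- rate_rows(ev[[r]][[a]], a, r)
      }
    }
    return(bind_rate_rows(out))
  }
  if (is.list(x)) {
    out <- lapply(x, function(st) rate_rows(st$event_log, st$agent,
                                            NA_integer_))
    return(bind_rate_rows(out))
  }
  stopf("unsupported input to innovation_rate_table")
}

rate_rows <- function(log, agent, replicate) {
  succ <- which(log$success)
  if (length(succ) == 0L) {
    return(data.frame(replicate = integer(0), agent = character(0),
                      rank = integer(0), failures_before = integer(0),
                      pool_size = integer(0),
                      possible_combinations = numeric(0),
                      stringsAsFactors = FALSE))
  }
  prev <- c(0L, succ[-length(succ)])
  data.frame(replicate = replicate, agent = agent,
             rank = seq_along(succ),
             failures_before = succ - prev - 1L,
             pool_size = log$pool_size[succ],
             possible_combinations = vapply(
               log$pool_size[succ],
               function(p) count_reachable_combinations(p, 4L), numeric(1)),
             stringsAsFactors = FALSE)
}

bind_rate_rows <- function(rows) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
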