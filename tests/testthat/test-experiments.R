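small_exp_config <- function(n_replicates = 3, seed = 5, ...) {
  experiment_config(
    tree = tree_gen_params(n_base = 4, n_intermediate = 8, n_logs = 6,
                           n_basic_logs = 2, min_basic_log_closure = 4),
    structure = population_structure("complete_group", group_size = 3),
    policy = agent_policy(unique_attempt_budget = 60),
    n_replicates = n_replicates, seed = seed, ...)
}

test_that("experiments are fully reproducible from the master seed", {
  r1 <- run_experiment(small_exp_config())
  r2 <- run_experiment(small_exp_config())
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 3 * 3) # one row per agent per replicate
  r3 <- run_experiment(small_exp_config(seed = 6))
  expect_false(isTRUE(all.equal(as.data.frame(r1), as.data.frame(r3))))
})

test_that("fixed-tree mode reuses one landscape across replicates", {
  cfg <- small_exp_config(fresh_tree = FALSE, keep_event_logs = TRUE)
  res <- run_experiment(cfg)
  expect_equal(nrow(res), 9)
  # identical tree means the recipe keys seen across replicates are drawn
  # from one recipe set; spot-check determinism instead: same config twice
  expect_equal(as.data.frame(run_experiment(cfg)), as.data.frame(res))
})

test_that("result rows are consistent with their event logs", {
  cfg <- small_exp_config(keep_event_logs = TRUE)
  res <- run_experiment(cfg)
  ev <- attr(res, "event_logs")
  for (i in seq_len(nrow(res))) {
    lg <- ev[[res$replicate[i]]][[res$agent[i]]]
    n_innov <- length(unique(stats::na.omit(lg$produced)))
    expect_equal(res$innovations[i], n_innov)
    expect_equal(res$final_score[i],
                 final_score(n_innov, res$best_totem_points[i]))
    expect_equal(anyDuplicated(lg$combination), 0)
  }
})

test_that("summary statistics match hand arithmetic", {
  tbl <- data.frame(final_score = c(0, 15, 30, 45),
                    built_totem = c(FALSE, FALSE, FALSE, TRUE),
                    innovations = c(0, 1, 2, 3))
  s <- summarize_results(tbl, n_boot = 200, seed = 1)
  expect_equal(s$mean_score, 22.5)
  expect_equal(s$sd_score, stats::sd(c(0, 15, 30, 45)))
  expect_equal(s$frac_totem, 0.25)
  expect_equal(s$mean_innovations, 1.5)
  expect_true(s$ci_lower <= s$mean_score && s$mean_score <= s$ci_upper)

  ten <- data.frame(final_score = rep(7, 10),
                    built_totem = c(TRUE, rep(FALSE, 9)),
                    innovations = rep(0, 10))
  s10 <- summarize_results(ten, n_boot = 50, seed = 2)
  expect_equal(s10$frac_totem, 0.1)
  expect_equal(s10$sd_score, 0)
  expect_equal(s10$ci_lower, 7) # degenerate CI at the mean
  expect_equal(s10$ci_upper, 7)
  expect_error(summarize_results(tbl[0, ]), "empty")
})

test_that("the innovation-rate table reproduces a hand-traced record", {
  lg <- data.frame(
    attempt = 1:6, epoch = 1,
    combination = paste0("c", 1:6),
    success = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    produced = c(NA, NA, "x", NA, "y", NA),
    pool_size = c(6, 6, 6, 7, 7, 8),
    collisions = 0, stringsAsFactors = FALSE)
  st <- structure(list(agent = "a1", produced = c("x", "y"),
                       attempted = lg$combination, event_log = lg,
                       exhausted = FALSE), class = "agent_state")
  tab <- innovation_rate_table(st)
  expect_equal(tab$rank, c(1, 2))
  expect_equal(tab$failures_before, c(2, 1))
  expect_equal(tab$pool_size, c(6, 7))
  expect_equal(tab$possible_combinations,
               c(count_reachable_combinations(6, 4),
                 count_reachable_combinations(7, 4)))

  none <- st
  none$event_log$success <- FALSE
  expect_equal(nrow(innovation_rate_table(none)), 0)
})

test_that("rate-table covariates agree with the counting operation on real runs", {
  st <- run_agent(fixture_generous_tree(),
                  agent_policy(unique_attempt_budget = 40), seed = 3)
  tab <- innovation_rate_table(st)
  expect_gt(nrow(tab), 0)
  expect_equal(tab$possible_combinations,
               vapply(tab$pool_size, function(p)
                 count_reachable_combinations(p, 4), numeric(1)))
  # ranks are 1..k in order and failure counts reconstruct attempt indices
  expect_equal(tab$rank, seq_len(nrow(tab)))
  succ_at <- cumsum(tab$failures_before + 1)
  expect_equal(succ_at, which(st$event_log$success))
})
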