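cli_path <- function() {
  system.file("cli", "totemsim.R", package = "totemsim")
}

run_cli <- function(...) {
  out <- suppressWarnings(system2("Rscript", c(cli_path(), ...),
                                  stdout = TRUE, stderr = TRUE))
  list(status = attr(out, "status") %||% 0L, output = out)
}

test_that("configurations are schema-validated with unknown keys rejected", {
  expect_s3_class(validate_run_config(list()), "run_config")
  ok <- list(tree = list(generate = list(n_base = 6)),
             experiment = list(n_replicates = 2, seed = 1))
  expect_s3_class(validate_run_config(ok), "run_config")
  expect_error(validate_run_config(list(turbo = list())), "unknown config")
  expect_error(validate_run_config(list(score = list(alpha = 3))),
               "unknown key")
  expect_error(validate_run_config(
    list(tree = list(generate = list(n_bases = 6)))), "tree.generate")
  expect_error(validate_run_config(
    list(tree = list(generate = list(n_base = 6), file = "x.json"))),
    "either")
})

test_that("a config file maps onto an experiment with the game's defaults", {
  path <- system.file("extdata", "example_config.yaml",
                      package = "totemsim")
  cfg <- read_run_config(path)
  ec <- config_to_experiment(cfg)
  expect_equal(ec$n_replicates, 10)
  expect_equal(ec$seed, 42)
  expect_equal(ec$policy$unique_attempt_budget, 188)
  expect_equal(ec$structure$variant, "isolated")
  expect_equal(ec$tree$n_logs, 115)
  expect_equal(ec$score$points_per_innovation, 15)
  expect_error(read_run_config("no/such/file.yaml"), "not found")
})

test_that("run_from_config writes results, summary and metadata", {
  dir <- withr::local_tempdir()
  cfg <- list(
    tree = list(generate = list(n_base = 4, n_intermediate = 8, n_logs = 6,
                                n_basic_logs = 2,
                                min_basic_log_closure = 4)),
    policy = list(unique_attempt_budget = 40),
    structure = list(variant = "isolated", group_size = 2),
    experiment = list(n_replicates = 2, seed = 7))
  paths <- run_from_config(cfg, out_dir = dir)
  expect_true(all(file.exists(paths)))
  res <- utils::read.csv(paths[["results"]])
  expect_equal(nrow(res), 4)
  expect_true(all(c("replicate", "agent", "innovations", "final_score")
                  %in% names(res)))
  s <- jsonlite::read_json(paths[["summary"]])
  expect_true(is.numeric(s$mean_score))
  # rerun is byte-identical on the results table
  dir2 <- withr::local_tempdir()
  paths2 <- run_from_config(cfg, out_dir = dir2)
  expect_identical(readLines(paths[["results"]]),
                   readLines(paths2[["results"]]))
})

test_that("the count subcommands print the landmark numbers", {
  r <- run_cli("count", "combos", "--pool", "6", "--slots", "4")
  expect_equal(r$status, 0L)
  expect_equal(utils::tail(r$output, 1), "209")
  r <- run_cli("count", "totems", "--logs", "115")
  expect_equal(r$status, 0L)
  expect_equal(utils::tail(r$output, 1), "266915")
  r <- run_cli("count", "combos", "--pool", "0")
  expect_equal(r$status, 2L)
})

test_that("tree generation and validation round-trip through the CLI", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "t1.json")
  f2 <- file.path(dir, "t2.json")
  r <- run_cli("generate-tree", "--out", f1, "--seed", "3")
  expect_equal(r$status, 0L)
  expect_equal(run_cli("generate-tree", "--out", f2, "--seed", "3")$status,
               0L)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(run_cli("validate-tree", "--tree", f1)$status, 0L)
  expect_equal(run_cli("validate-tree", "--tree",
                       file.path(dir, "missing.json"))$status, 1L)
})

test_that("the run subcommand produces schema-valid outputs", {
  dir <- withr::local_tempdir()
  cfg_file <- file.path(dir, "cfg.yaml")
  writeLines(c("tree:",
               "  generate: {n_base: 4, n_intermediate: 8, n_logs: 6,",
               "             n_basic_logs: 2, min_basic_log_closure: 4}",
               "policy: {unique_attempt_budget: 40}",
               "structure: {variant: isolated, group_size: 2}",
               "experiment: {n_replicates: 2, seed: 9}"), cfg_file)
  r <- run_cli("run", "--config", cfg_file, "--out-dir",
               file.path(dir, "out"))
  expect_equal(r$status, 0L)
  expect_true(file.exists(file.path(dir, "out", "results.csv")))
  expect_true(file.exists(file.path(dir, "out", "summary.json")))
  # malformed config: unknown key, nonzero exit, distinct from runtime
  bad_file <- file.path(dir, "bad.yaml")
  writeLines("bogus_section: {a: 1}", bad_file)
  expect_equal(run_cli("run", "--config", bad_file)$status, 2L)
})
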