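test_that("population structures validate their sizes", {
  expect_error(population_structure("metapopulation", group_size = 5),
               "inconsistent sizes")
  expect_error(population_structure("complete_group", n_epochs = 0),
               "n_epochs")
  s <- population_structure("metapopulation")
  expect_equal(s$group_size, 6)
})

test_that("complete groups see all others in every epoch", {
  s <- population_structure("complete_group", group_size = 6)
  sch <- build_schedule(s, seed = 1)
  expect_length(sch$epochs, 15)
  for (e in seq_along(sch$epochs)) {
    for (a in names(sch$epochs[[e]])) {
      expect_setequal(sch$epochs[[e]][[a]],
                      setdiff(paste0("a", 1:6), a))
    }
  }
})

test_that("metapopulation epochs are perfect matchings with reciprocal ties", {
  s <- population_structure("metapopulation")
  sch <- build_schedule(s, seed = 2)
  for (e in seq_along(sch$epochs)) {
    nb <- sch$epochs[[e]]
    expect_true(all(lengths(nb) == 1)) # pairs: exactly one partner
    for (a in names(nb)) {
      expect_true(a %in% nb[[nb[[a]]]]) # reciprocity
    }
    # three disjoint pairs partition the six agents
    expect_setequal(unlist(nb), paste0("a", 1:6))
  }
})

test_that("isolated schedules have empty neighborhoods", {
  sch <- build_schedule(population_structure("isolated", group_size = 3),
                        seed = 1)
  expect_true(all(lengths(sch$epochs[[1]]) == 0))
  expect_equal(nrow(schedule_to_df(sch)), 0)
})

test_that("matchings are uniform and partners are uniform marginally", {
  s <- population_structure("metapopulation", n_epochs = 1)
  n_draws <- 10000
  partner_of_a1 <- character(n_draws)
  matching_key <- character(n_draws)
  withr::with_seed(31, {
    for (i in seq_len(n_draws)) {
      nb <- build_schedule_impl(s)$epochs[[1]]
      partner_of_a1[i] <- nb[["a1"]]
      matching_key[i] <- paste(vapply(paste0("a", 1:6), function(a)
        nb[[a]], character(1)), collapse = ",")
    }
  })
  # marginal: a1's partner uniform over the 5 others
  p <- stats::chisq.test(table(partner_of_a1))$p.value
  expect_gt(p, 1e-4)
  # joint: all 15 perfect matchings on 6 agents, uniformly
  tab <- table(matching_key)
  expect_equal(length(tab), 15)
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
})

test_that("every pair connects within 15 epochs at the predicted rate", {
  s <- population_structure("metapopulation", n_epochs = 15)
  n_sched <- 2000
  withr::with_seed(7, {
    ever <- vapply(seq_len(n_sched), function(i) {
      sch <- build_schedule_impl(s)
      any(vapply(sch$epochs, function(nb) nb[["a1"]] == "a2", logical(1)))
    }, logical(1))
  })
  p_expected <- 1 - (4 / 5)^15 # partner uniform among 5, 15 epochs
  se <- sqrt(p_expected * (1 - p_expected) / n_sched)
  expect_lt(abs(mean(ever) - p_expected), 5 * se)
})

test_that("visibility follows the population structure", {
  tr <- fixture_generous_tree()
  produced <- list(a1 = c("i1"), a2 = c("i2"), a3 = character(0),
                   a4 = c("i3"), a5 = character(0), a6 = character(0))

  iso <- build_schedule(population_structure("isolated", group_size = 6),
                        seed = 1)
  expect_setequal(visible_items(tr, "a1", 1, iso, produced),
                  c(tr$base_ids, "i1"))

  full <- build_schedule(population_structure("complete_group",
                                              group_size = 6), seed = 1)
  expect_setequal(visible_items(tr, "a3", 1, full, produced),
                  c(tr$base_ids, "i1", "i2", "i3"))

  meta <- build_schedule(population_structure("metapopulation"), seed = 3)
  partner <- meta$epochs[[1]][["a1"]]
  expect_setequal(visible_items(tr, "a1", 1, meta, produced),
                  unique(c(tr$base_ids, "i1", produced[[partner]])))
  expect_error(visible_items(tr, "a1", 99, meta, produced), "epoch")
  expect_error(visible_items(tr, "zz", 1, meta, produced), "unknown agent")
})

test_that("retention keeps ever-seen neighbors' items visible", {
  tr <- fixture_generous_tree()
  s <- population_structure("metapopulation", retention = TRUE)
  sch <- build_schedule(s, seed = 11)
  produced <- stats::setNames(lapply(paste0("i", 1:6), function(x)
    if (x %in% c("i1", "i2", "i3")) x else character(0)), paste0("a", 1:6))
  p1 <- sch$epochs[[1]][["a1"]]
  # at epoch 1 retention equals the current neighborhood
  expect_setequal(visible_items(tr, "a1", 1, sch, produced),
                  unique(c(tr$base_ids, produced[["a1"]], produced[[p1]])))
  # by the last epoch the visible set can only have grown
  v_last <- visible_items(tr, "a1", 15, sch, produced)
  expect_true(all(visible_items(tr, "a1", 1, sch, produced) %in% v_last))
})

test_that("population runs are deterministic with fair budget splits", {
  tr <- small_tree(6)
  s <- population_structure("complete_group", group_size = 3, n_epochs = 15)
  r1 <- run_population(tr, s, agent_policy(), seed = 10)
  r2 <- run_population(tr, s, agent_policy(), seed = 10)
  expect_identical(lapply(r1, `[[`, "event_log"),
                   lapply(r2, `[[`, "event_log"))
  for (a in names(r1)) {
    lg <- r1[[a]]$event_log
    expect_equal(nrow(lg), 188) # full budget, no exhaustion
    # epoch allocation: ceil for the first epochs, floor afterwards
    expect_equal(unname(table(lg$epoch)),
                 rep(c(13, 12), c(188 %% 15, 15 - 188 %% 15)),
                 ignore_attr = TRUE)
  }
})

test_that("social learning never hurts innovation on average", {
  n_rep <- 30
  iso_mean <- grp_mean <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    tr <- generate_tree(tree_gen_params(seed = 1000 + i))
    iso <- run_population(tr, population_structure("isolated",
                                                   group_size = 6),
                          agent_policy(), seed = 500 + i)
    grp <- run_population(tr, population_structure("complete_group",
                                                   group_size = 6),
                          agent_policy(), seed = 500 + i)
    iso_mean[i] <- mean(vapply(iso, function(s) length(s$produced),
                               integer(1)))
    grp_mean[i] <- mean(vapply(grp, function(s) length(s$produced),
                               integer(1)))
  }
  expect_gte(mean(grp_mean), mean(iso_mean))
})
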