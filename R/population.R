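#' Population structure of a simulation run
#'
#' Three variants cover the experimental designs: `isolated` agents (no
#' social information), a `complete_group` where every agent permanently
#' sees every other member's innovations, and a `metapopulation` in which
#' the agents are re-partitioned at random into subgroups at every epoch
#' with reciprocal ties (the 3 x 2 default: six agents split into three
#' pairs, re-drawn each epoch).  A 45-minute session with ties rotating
#' every 3 minutes gives the default of 15 epochs.
#'
#' @param variant One of `"isolated"`, `"complete_group"`,
#'   `"metapopulation"`.
#' @param group_size Number of agents for `isolated` (independent agents,
#'   default 1) and `complete_group` (default 6).
#' @param n_subgroups,subgroup_size Metapopulation layout (default 3 x 2).
#' @param n_epochs Number of tie-rotation epochs (default 15).
#' @param retention Keep social items visible after a tie is dropped?
#'   Default `FALSE`: an item another agent produced is usable only while
#'   its producer is a current neighbor (unless personally produced).
#' @return An object of class `population_structure`.
#' @export
population_structure <- function(variant = c("isolated", "complete_group",
                                             "metapopulation"),
                                 group_size = NULL, n_subgroups = 3,
                                 subgroup_size = 2, n_epochs = 15,
                                 retention = FALSE) {
  variant <- match.arg(variant)
  if (n_epochs < 1) stopf("n_epochs must be >= 1")
  if (variant == "metapopulation") {
    n_subgroups <- as.integer(n_subgroups)
    subgroup_size <- as.integer(subgroup_size)
    if (n_subgroups < 1 || subgroup_size < 1) {
      stopf("metapopulation sizes must be positive")
    }
    if (!is.null(group_size) &&
        group_size != n_subgroups * subgroup_size) {
      stopf("inconsistent sizes: group_size %d != %d subgroups x %d",
            group_size, n_subgroups, subgroup_size)
    }
    group_size <- n_subgroups * subgroup_size
  } else {
    group_size <- as.integer(group_size %||%
                               if (variant == "isolated") 1L else 6L)
    if (group_size < 1) stopf("group_size must be >= 1")
  }
  structure(list(variant = variant, group_size = as.integer(group_size),
                 n_subgroups = if (variant == "metapopulation") n_subgroups
                 else NULL,
                 subgroup_size = if (variant == "metapopulation")
                   subgroup_size else NULL,
                 n_epochs = as.integer(n_epochs),
                 retention = isTRUE(retention)),
            class = "population_structure")
}

n_agents <- function(structure) structure$group_size

agent_names <- function(structure) paste0("a", seq_len(n_agents(structure)))

#' Build a tie schedule realizing a population structure
#'
#' Isolated agents get empty neighborhoods in every epoch; a complete
#' group connects every agent to all others in every epoch; a
#' metapopulation draws an independent uniform random partition of the
#' agents into subgroups at each epoch (a uniform perfect matching when
#' subgroups have size 2).  Ties are reciprocal by construction.
#'
#' @param structure A [population_structure()].
#' @param seed Optional integer seed.
#' @return An object of class `tie_schedule`: list with `epochs`, a list
#'   (one per epoch) of named lists mapping each agent to the character
#'   vector of its neighbors.
#' @export
build_schedule <- function(structure, seed = NULL) {
  with_seed_or_stream(seed, build_schedule_impl(structure))
}

build_schedule_impl <- function(structure) {
  ags <- agent_names(structure)
  n <- length(ags)
  epochs <- vector("list", structure$n_epochs)
  for (e in seq_len(structure$n_epochs)) {
    nb <- switch(structure$variant,
      isolated = stats::setNames(rep(list(character(0)), n), ags),
      complete_group = stats::setNames(
        lapply(ags, function(a) setdiff(ags, a)), ags),
      metapopulation = {
        # uniform random partition into subgroups: shuffle, then chunk
        # (every partition arises from the same number of permutations)
        perm <- ags[sample.int(n)]
        groups <- split(perm, rep(seq_len(structure$n_subgroups),
                                  each = structure$subgroup_size))
        out <- stats::setNames(vector("list", n), ags)
        for (g in groups) for (a in g) out[[a]] <- setdiff(g, a)
        out
      })
    epochs[[e]] <- nb
  }
  structure(list(epochs = epochs, structure = structure),
            class = "tie_schedule")
}

#' Tie schedule as a long data frame
#'
#' @param schedule A `tie_schedule`.
#' @return data.frame with columns epoch, agent, neighbor (one row per
#'   directed tie; reciprocity means every tie appears in both
#'   directions).
#' @export
schedule_to_df <- function(schedule) {
  rows <- list()
  for (e in seq_along(schedule$epochs)) {
    nb <- schedule$epochs[[e]]
    for (a in names(nb)) {
      if (length(nb[[a]]) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          epoch = e, agent = a, neighbor = nb[[a]],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(epoch = integer(0), agent = character(0),
                      neighbor = character(0)))
  }
  do.call(rbind, rows)
}

#' Items visible to an agent at an epoch
#'
#' The base resources, the agent's own produced items, and the produced
#' items of its neighbors: the current epoch's neighbors under the
#' default no-retention policy, or every agent that has ever been a
#' neighbor up to this epoch when `retention` is set on the structure.
#'
#' @param tree A `techtree`.
#' @param agent Agent name (e.g. `"a1"`).
#' @param epoch Epoch number, within the schedule.
#' @param schedule A `tie_schedule`.
#' @param produced Named list mapping each agent to the character vector
#'   of items it has produced.
#' @return Character vector of visible item ids.
#' @export
visible_items <- function(tree, agent, epoch, schedule, produced) {
  if (epoch < 1 || epoch > length(schedule$epochs)) {
    stopf("epoch %s outside the schedule (1..%d)", epoch,
          length(schedule$epochs))
  }
  if (!agent %in% names(schedule$epochs[[1]])) {
    stopf("unknown agent: %s", agent)
  }
  nbrs <- if (isTRUE(schedule$structure$retention)) {
    unique(unlist(lapply(seq_len(epoch), function(e)
      schedule$epochs[[e]][[agent]])))
  } else {
    schedule$epochs[[epoch]][[agent]]
  }
  unique(c(tree$base_ids, produced[[agent]],
           unlist(produced[nbrs], use.names = FALSE)))
}

#' Run a population of agents on a tree
#'
#' Every agent spends the same unique-attempt budget, split evenly across
#' the epochs (the integer remainder goes to the earliest epochs), and the
#' agents advance round-robin within an epoch so attempt counts never
#' differ by more than one.  Discoveries are shared instantly within the
#' current neighborhoods.  Identical seeds give identical event logs.
#'
#' @param tree A `techtree`.
#' @param structure A [population_structure()].
#' @param policy An [agent_policy()].
#' @param seed Optional integer seed.
#' @param schedule Optional pre-built `tie_schedule` (drawn from the same
#'   stream when omitted).
#' @return List of `agent_state` objects, one per agent, named by agent.
#' @export
run_population <- function(tree, structure = population_structure(),
                           policy = agent_policy(), seed = NULL,
                           schedule = NULL) {
  with_seed_or_stream(seed,
                      run_population_impl(tree, structure, policy, schedule))
}

# The hot loop encodes items as integer ranks in sorted-id order and a
# combination as a base-M number over its (ascending) ranks, zero-padded
# to 4 digits.  Integer-rank sorting agrees with the canonical sorted-id
# order, so the numeric key is a bijective image of the canonical
# multiset key; strings are only materialized when the event logs are
# assembled at the end of the run.
run_population_impl <- function(tree, structure, policy, schedule = NULL) {
  ags <- agent_names(structure)
  n <- length(ags)
  if (is.null(schedule)) schedule <- build_schedule_impl(structure)
  budget <- policy$unique_attempt_budget
  n_ep <- structure$n_epochs
  alloc <- rep(budget %/% n_ep, n_ep) +
    (seq_len(n_ep) <= budget %% n_ep)

  ids_sorted <- sort(tree$items$id)
  M <- length(ids_sorted) + 1
  encode <- function(ranks) { # ranks ascending, length 1..4
    d <- c(integer(4L - length(ranks)), ranks)
    ((d[1] * M + d[2]) * M + d[3]) * M + d[4]
  }
  ridx <- new.env(parent = emptyenv(), size = 512L)
  for (out in names(tree$recipes)) {
    r <- sort(match(tree$recipes[[out]], ids_sorted))
    ridx[[as.character(encode(r))]] <- match(out, ids_sorted)
  }
  base_ranks <- match(tree$base_ids, ids_sorted)

  produced <- rep(list(integer(0)), n) # discovery order, as ranks
  produced_flag <- matrix(FALSE, length(ids_sorted), n)
  attempted <- lapply(seq_len(n), function(i) new.env(parent = emptyenv()))
  # event logs as preallocated budget x n_agents matrices (in-place writes)
  ev_epoch <- matrix(0L, budget, n)
  ev_key <- matrix(0, budget, n)
  ev_success <- matrix(FALSE, budget, n)
  ev_produced <- matrix(0L, budget, n)
  ev_pool <- matrix(0L, budget, n)
  ev_coll <- matrix(0L, budget, n)
  ev_n <- integer(n)
  exhausted <- rep(FALSE, n)
  ever_nbrs <- rep(list(integer(0)), n)

  # Visibility fast paths: for isolated agents the pool is base + own
  # produced; for a complete group it is one shared pool every member
  # sees; the metapopulation recomputes small unions per attempt.
  complete <- structure$variant == "complete_group"
  isolated <- structure$variant == "isolated"
  shared_pool <- base_ranks
  shared_flag <- logical(length(ids_sorted))
  own_pool <- rep(list(base_ranks), n)

  for (e in seq_len(n_ep)) {
    nb <- lapply(schedule$epochs[[e]], function(x) match(x, ags))
    if (structure$retention) {
      for (ai in seq_len(n)) {
        ever_nbrs[[ai]] <- unique(c(ever_nbrs[[ai]], nb[[ai]]))
      }
      nbrs <- ever_nbrs
    } else {
      nbrs <- nb
    }
    for (t in seq_len(alloc[e])) {
      for (ai in seq_len(n)) {
        if (exhausted[ai]) next
        pool <- if (isolated) own_pool[[ai]]
          else if (complete) shared_pool
          else unique(c(own_pool[[ai]],
                        unlist(produced[nbrs[[ai]]], use.names = FALSE)))
        np <- length(pool)
        att <- attempted[[ai]]
        collisions <- 0L
        key_chr <- NULL
        repeat {
          k <- sample.int(4L, 1L)
          sel <- sample.int(np, k, replace = TRUE)
          # inline sorting network (k <= 4) + base-M key arithmetic;
          # equals encode(sort(pool[sel])) but without sort() dispatch
          if (k == 1L) {
            key <- pool[sel]
          } else if (k == 2L) {
            a <- pool[sel[1L]]; b <- pool[sel[2L]]
            if (a > b) { tt <- a; a <- b; b <- tt }
            key <- a * M + b
          } else if (k == 3L) {
            a <- pool[sel[1L]]; b <- pool[sel[2L]]; cc <- pool[sel[3L]]
            if (a > b) { tt <- a; a <- b; b <- tt }
            if (b > cc) { tt <- b; b <- cc; cc <- tt }
            if (a > b) { tt <- a; a <- b; b <- tt }
            key <- (a * M + b) * M + cc
          } else {
            a <- pool[sel[1L]]; b <- pool[sel[2L]]
            cc <- pool[sel[3L]]; d <- pool[sel[4L]]
            if (a > b) { tt <- a; a <- b; b <- tt }
            if (cc > d) { tt <- cc; cc <- d; d <- tt }
            if (a > cc) { tt <- a; a <- cc; cc <- tt }
            if (b > d) { tt <- b; b <- d; d <- tt }
            if (b > cc) { tt <- b; b <- cc; cc <- tt }
            key <- ((a * M + b) * M + cc) * M + d
          }
          kc <- as.character(key)
          if (is.null(att[[kc]])) { key_chr <- kc; break }
          collisions <- collisions + 1L
          if (collisions >= 1000L) {
            alt <- exact_untried_draw(pool, att, encode)
            if (is.null(alt)) break
            key_chr <- alt$key
            break
          }
        }
        if (is.null(key_chr)) { exhausted[ai] <- TRUE; next }
        att[[key_chr]] <- TRUE
        out <- ridx[[key_chr]]
        i <- ev_n[ai] + 1L
        ev_epoch[i, ai] <- e
        ev_key[i, ai] <- as.numeric(key_chr)
        ev_success[i, ai] <- !is.null(out)
        ev_pool[i, ai] <- np
        ev_coll[i, ai] <- collisions
        ev_n[ai] <- i
        if (!is.null(out)) {
          ev_produced[i, ai] <- out
          if (!produced_flag[out, ai]) {
            produced_flag[out, ai] <- TRUE
            produced[[ai]] <- c(produced[[ai]], out)
            own_pool[[ai]] <- c(own_pool[[ai]], out)
          }
          if (complete && !shared_flag[out]) {
            shared_flag[out] <- TRUE
            shared_pool <- c(shared_pool, out)
          }
        }
      }
    }
  }

  decode_keys <- function(keys) { # vectorized numeric key -> "a|b" string
    d4 <- keys %% M; keys <- keys %/% M
    d3 <- keys %% M; keys <- keys %/% M
    d2 <- keys %% M; d1 <- keys %/% M
    part <- function(d) ifelse(d > 0, paste0(ids_sorted[pmax(d, 1)], "|"),
                               "")
    # d4 is always non-zero (the largest-position digit of a non-empty
    # multiset); strip nothing else
    paste0(part(d1), part(d2), part(d3), ids_sorted[d4])
  }

  stats::setNames(lapply(seq_len(n), function(ai) {
    m <- ev_n[ai]
    idx <- seq_len(m)
    prod_ranks <- ev_produced[idx, ai]
    prod_ids <- rep(NA_character_, m)
    prod_ids[prod_ranks > 0L] <- ids_sorted[prod_ranks[prod_ranks > 0L]]
    structure(list(
      agent = ags[ai],
      produced = ids_sorted[produced[[ai]]],
      attempted = if (m > 0) decode_keys(ev_key[idx, ai]) else character(0),
      event_log = structure(list(
        attempt = idx,
        epoch = ev_epoch[idx, ai],
        combination = if (m > 0) decode_keys(ev_key[idx, ai]) else
          character(0),
        success = ev_success[idx, ai],
        produced = prod_ids,
        pool_size = ev_pool[idx, ai],
        collisions = ev_coll[idx, ai]),
        class = "data.frame", row.names = c(NA_integer_, -m)),
      exhausted = exhausted[ai]),
      class = "agent_state")
  }), ags)
}

# Exact fallback when rejection keeps colliding on a nearly exhausted
# pool: enumerate the untried multisets over `pool` (ranks) and draw one
# from the exact conditional candidate distribution.  NULL when the
# design space over the pool is exhausted.
exact_untried_draw <- function(pool, attempted, encode) {
  pool <- sort.int(unique(pool))
  n_space <- count_reachable_combinations(length(pool), 4L)
  if (n_space > 1e5) {
    stopf("pool too large for exact exhaustion check (%d combinations)",
          n_space)
  }
  all_ms <- enumerate_multisets(pool, 4L)
  keys <- vapply(all_ms, function(ms) as.character(encode(ms)), character(1))
  untried <- vapply(keys, function(kk) is.null(attempted[[kk]]), logical(1))
  if (!any(untried)) return(NULL)
  rem <- all_ms[untried]
  # draw probability of a multiset of size k with multiplicities m:
  # (1/4) * (k! / prod(m!)) / pool^k
  w <- vapply(rem, function(ms) {
    k <- length(ms)
    m <- table(ms)
    exp(lfactorial(k) - sum(lfactorial(m)) - k * log(length(pool)))
  }, numeric(1))
  j <- sample.int(length(rem), 1L, prob = w)
  list(key = keys[untried][j], ranks = rem[[j]])
}

#' @export
print.agent_state <- function(x, ...) {
  cat(sprintf(
    "Agent %s: %d unique attempts, %d innovations%s\n", x$agent,
    nrow(x$event_log), length(x$produced),
    if (x$exhausted) " (design space exhausted)" else ""))
  invisible(x)
}
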