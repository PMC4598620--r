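#' Random-search agent policy
#'
#' Bots explore the innovation landscape by undirected random search: for
#' each attempt they first draw a slot count `N` uniformly from 1-4, then
#' draw `N` items independently and uniformly with replacement from their
#' currently visible item pool.  Attempts are deduplicated per agent at no
#' cost: colliding with an already-tried combination does not consume
#' budget, so each agent performs exactly `unique_attempt_budget` distinct
#' attempts (188 by default, the empirical mean number of unique
#' combinations humans produced in a 45-minute session).
#'
#' @param unique_attempt_budget Number of distinct combinations the agent
#'   may try (default 188).
#' @param totem_from_visible Should the agent's totem be scored over every
#'   log it can see (`TRUE`) or only over logs it produced itself
#'   (default `FALSE`)?
#' @return An object of class `agent_policy`.
#' @export
agent_policy <- function(unique_attempt_budget = 188,
                         totem_from_visible = FALSE) {
  if (unique_attempt_budget < 1) stopf("unique_attempt_budget must be >= 1")
  structure(list(unique_attempt_budget = as.integer(unique_attempt_budget),
                 totem_from_visible = isTRUE(totem_from_visible)),
            class = "agent_policy")
}

#' Draw one random workshop candidate from a pool
#'
#' Slot count uniform on 1-4, then independent uniform draws with
#' replacement from `pool`; the result is canonical.  Note the induced
#' distribution over multisets is not uniform: ordered draws that
#' canonicalize to the same multiset pool their probability, so e.g. with
#' pool `{a, b}` the single-item combination `{a}` has probability
#' `1/4 * 1/2 = 1/8` while `{a, b}` has `1/4 * 2/4 = 1/8` as well but
#' `{a, a}` only `1/16`.
#'
#' @param pool Non-empty character vector of visible item ids.
#' @return A canonical `combination`.
#' @export
draw_candidate <- function(pool) {
  if (length(pool) == 0L) stopf("cannot draw a combination from an empty pool")
  n <- sample.int(4L, 1L)
  canonicalize(pool[sample.int(length(pool), n, replace = TRUE)])
}

# One unique candidate over `pool` given the set of `attempted` keys (an
# environment).  Rejection-samples draw_candidate; after `max_collisions`
# consecutive collisions it falls back to exact enumeration of the
# remaining untried multisets and samples one from the exact conditional
# distribution (so the fallback does not distort the search process).
# Errors when the design space over the current pool is exhausted.
next_unique_candidate <- function(pool, attempted, max_collisions = 1000L) {
  pool <- sort(unique(pool))
  n_space <- count_reachable_combinations(length(pool), 4L)
  collisions <- 0L
  repeat {
    n <- sample.int(4L, 1L)
    comb <- sort(pool[sample.int(length(pool), n, replace = TRUE)])
    key <- paste(comb, collapse = "|")
    if (is.null(attempted[[key]])) {
      return(list(combination = comb, key = key, collisions = collisions))
    }
    collisions <- collisions + 1L
    if (collisions >= max_collisions && n_space <= 1e5) {
      all_ms <- enumerate_multisets(pool, 4L)
      keys <- vapply(all_ms, paste, character(1), collapse = "|")
      untried <- vapply(keys, function(k) is.null(attempted[[k]]),
                        logical(1))
      if (!any(untried)) {
        stopf("design space exhausted: all %d combinations over the %d-item pool were attempted",
              n_space, length(pool))
      }
      rem <- all_ms[untried]
      # exact conditional draw probability of a multiset of size k with
      # multiplicities m: (1/4) * (k! / prod(m!)) / pool^k
      w <- vapply(rem, function(ms) {
        k <- length(ms)
        m <- table(ms)
        exp(lfactorial(k) - sum(lfactorial(m)) - k * log(length(pool)))
      }, numeric(1))
      j <- sample.int(length(rem), 1L, prob = w)
      return(list(combination = rem[[j]], key = keys[untried][j],
                  collisions = collisions))
    }
  }
}

#' Next untried combination for an agent
#'
#' Draws candidates until one not already in the agent's attempt history
#' appears.  Collisions cost nothing; they are only counted for
#' diagnostics.  Errors when every combination over the current pool has
#' been tried.
#'
#' @param attempted Character vector of canonical combination keys already
#'   tried (as produced by `paste(combination, collapse = "|")`).
#' @param pool Currently visible item ids.
#' @return A canonical `combination`.
#' @export
next_unique_attempt <- function(attempted, pool) {
  env <- new.env(parent = emptyenv())
  for (k in attempted) env[[k]] <- TRUE
  canonicalize(next_unique_candidate(pool, env)$combination)
}

#' Run a single isolated agent
#'
#' Executes the agent's full unique-attempt budget against a tree:
#' successful combinations add their output to the agent's personal pool,
#' immediately usable in subsequent attempts.  Identical seeds reproduce
#' the identical event log.  If the design space over the pool is ever
#' exhausted (possible only on very small trees) the run ends early and
#' the exhaustion is recorded.
#'
#' @param tree A `techtree`.
#' @param policy An [agent_policy()].
#' @param seed Optional integer seed.
#' @return An object of class `agent_state`: list with `produced`
#'   (character vector of items the agent made, in discovery order),
#'   `attempted` (character vector of canonical keys), `event_log`
#'   (data.frame: attempt, epoch, combination, success, produced,
#'   pool_size, collisions), and `exhausted` (logical).
#' @export
run_agent <- function(tree, policy = agent_policy(), seed = NULL) {
  with_seed_or_stream(seed, {
    states <- run_population_impl(tree, population_structure("isolated",
                                                             group_size = 1),
                                  policy)
    states[[1]]
  })
}
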