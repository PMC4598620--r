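#' Parameters for technology-tree generation
#'
#' A technology tree is the innovation landscape of the game: a set of
#' items partitioned into base resources (freely available), intermediate
#' items (tools and parts) and logs (the elements of a totem), with exactly
#' one crafting recipe per non-base item.  The defaults reproduce the
#' structure of the original game: 6 base resources, 27 intermediates and
#' 115 logs, hence 142 recipes in total, with at least one "basic" log
#' whose production requires at least eight innovations.
#'
#' @param n_base Number of base resources (default 6).
#' @param n_intermediate Number of intermediate items (default 27).
#' @param n_logs Number of log items (default 115).
#' @param n_basic_logs Number of logs craftable without using another log
#'   (default 1); the remaining logs are refinements of existing logs.
#' @param min_basic_log_closure Minimum complexity (innovation-closure
#'   size) of every basic log (default 8).
#' @param max_inputs Workshop slot count, the maximum recipe size
#'   (default 4).
#' @param seed Optional integer seed; identical seed and parameters yield
#'   a bit-identical tree.
#' @return An object of class `tree_gen_params`.
#' @export
tree_gen_params <- function(n_base = 6, n_intermediate = 27, n_logs = 115,
                            n_basic_logs = 1, min_basic_log_closure = 8,
                            max_inputs = 4, seed = NULL) {
  p <- list(n_base = as.integer(n_base),
            n_intermediate = as.integer(n_intermediate),
            n_logs = as.integer(n_logs),
            n_basic_logs = as.integer(n_basic_logs),
            min_basic_log_closure = as.integer(min_basic_log_closure),
            max_inputs = as.integer(max_inputs),
            seed = if (is.null(seed)) NULL else as.integer(seed))
  if (p$n_base < 1) stopf("n_base must be >= 1")
  if (p$n_intermediate < 0) stopf("n_intermediate must be >= 0")
  if (p$n_logs < 0) stopf("n_logs must be >= 0")
  if (p$n_logs >= 1 && p$n_basic_logs < 1) {
    stopf("n_basic_logs must be >= 1 when the tree has logs")
  }
  if (p$n_basic_logs > p$n_logs) stopf("n_basic_logs cannot exceed n_logs")
  if (p$min_basic_log_closure < 1) stopf("min_basic_log_closure must be >= 1")
  if (p$max_inputs < 1) stopf("max_inputs must be >= 1")
  structure(p, class = "tree_gen_params")
}

new_techtree <- function(items, recipes, base_ids, basic_log_ids, params,
                         log_values = NULL, closures = NULL) {
  structure(list(items = items, recipes = recipes, base_ids = base_ids,
                 basic_log_ids = basic_log_ids, params = params,
                 log_values = log_values, closures = closures),
            class = "techtree")
}

#' @export
print.techtree <- function(x, ...) {
  k <- table(factor(x$items$kind, levels = c("base", "intermediate", "log")))
  cat(sprintf(
    "Technology tree: %d base, %d intermediate, %d log items (%d recipes)\n",
    k[["base"]], k[["intermediate"]], k[["log"]], length(x$recipes)))
  if (!is.null(x$log_values)) {
    cat(sprintf("Log values assigned: %d logs, range [%g, %g]\n",
                length(x$log_values), min(x$log_values), max(x$log_values)))
  }
  invisible(x)
}

item_ids_of_kind <- function(tree, kind) {
  tree$items$id[tree$items$kind == kind]
}

#' Item identifiers of a tree, by kind
#'
#' @param tree A `techtree`.
#' @return Character vector of item ids.
#' @name tree-accessors
NULL

#' @rdname tree-accessors
#' @export
tree_base_ids <- function(tree) tree$base_ids

#' @rdname tree-accessors
#' @export
tree_log_ids <- function(tree) item_ids_of_kind(tree, "log")

#' @rdname tree-accessors
#' @export
tree_intermediate_ids <- function(tree) item_ids_of_kind(tree, "intermediate")

# Closures of every item, computed by a forward-production sweep from the
# base resources: repeatedly execute every recipe whose inputs are all
# producible.  An item's innovation closure is itself plus the union of its
# inputs' closures; items a cyclic or disconnected recipe set cannot reach
# get NULL.  Returns a named list id -> sorted character vector.
# Trees built by generate_tree() carry a cache; validation bypasses it.
all_closures <- function(tree, use_cache = TRUE) {
  if (use_cache && !is.null(tree$closures)) return(tree$closures)
  closures <- stats::setNames(vector("list", nrow(tree$items)),
                              tree$items$id)
  for (b in tree$base_ids) closures[[b]] <- character(0)
  pending <- setdiff(tree$items$id, tree$base_ids)
  repeat {
    progressed <- FALSE
    still <- character(0)
    for (id in pending) {
      rec <- tree$recipes[[id]]
      if (is.null(rec)) { still <- c(still, id); next }
      ins <- unique(rec)
      if (all(vapply(ins, function(i) !is.null(closures[[i]]) ||
                       i %in% tree$base_ids, logical(1)))) {
        cl <- unique(c(id, unlist(closures[ins], use.names = FALSE)))
        closures[[id]] <- sort(cl)
        progressed <- TRUE
      } else {
        still <- c(still, id)
      }
    }
    pending <- still
    if (!progressed || length(pending) == 0L) break
  }
  closures
}

#' Innovation closure and complexity of an item
#'
#' The innovation closure of an item is the minimal set of non-base items
#' whose recipes must all be executed to produce it from the base
#' resources, including the item itself when it is not a base resource.
#' Its size is the item's complexity — the number of innovations the item
#' embodies.  Base resources have an empty closure and complexity zero.
#'
#' @param tree A `techtree`.
#' @param item_id A single item id present in the tree.
#' @return `innovation_closure()`: sorted character vector of item ids;
#'   `item_complexity()`: its length.
#' @export
innovation_closure <- function(tree, item_id) {
  if (!item_id %in% tree$items$id) stopf("unknown item id: %s", item_id)
  if (item_id %in% tree$base_ids) return(character(0))
  cl <- all_closures(tree)[[item_id]]
  if (is.null(cl)) stopf("item %s is not producible from base resources",
                         item_id)
  cl
}

#' @rdname innovation_closure
#' @export
item_complexity <- function(tree, item_id) {
  length(innovation_closure(tree, item_id))
}

# Draw one untried recipe-input multiset over `avail` with sampling weights
# `w`, rejecting keys present in `used`.  Rejection is capped; feasibility
# of the parameter set is the caller's contract.
draw_new_multiset <- function(avail, w, max_inputs, used, max_tries = 2000L,
                              force_include = character(0)) {
  n_free <- max_inputs - length(force_include)
  if (n_free <= 0L) {
    inputs <- sort(force_include)
    key <- multiset_key(inputs)
    if (is.null(used[[key]])) return(list(inputs = inputs, key = key))
    stopf("tree generation infeasible: forced input multiset already in use")
  }
  for (i in seq_len(max_tries)) {
    k <- sample.int(n_free, 1L)
    pick <- avail[sample.int(length(avail), k, replace = TRUE, prob = w)]
    inputs <- sort(c(force_include, pick))
    key <- multiset_key(inputs)
    if (is.null(used[[key]])) return(list(inputs = inputs, key = key))
  }
  stopf(paste0("tree generation infeasible: could not find an unused input",
               " multiset (pool %d items, %d slots); increase the item pool",
               " or reduce the recipe count"),
        length(avail), max_inputs)
}

#' Generate a random technology tree
#'
#' Builds a tree satisfying all structural invariants of the game:
#' acyclic recipes, every non-base item reachable from the base resources,
#' every intermediate useful (contained in at least one log's closure),
#' one recipe per non-base item with a globally unique input multiset, and
#' every basic log at least `min_basic_log_closure` innovations deep.
#' Intermediates are created layer by layer with inputs drawn from the
#' items already placed, weighted towards complex items so that deep
#' production chains form; the first `min_basic_log_closure - 1`
#' intermediates form a guaranteed spine of strictly increasing depth.
#' Non-basic logs are refinements: each combines one existing log with
#' intermediate items, mirroring log refinement with tools.
#'
#' @param params A [tree_gen_params()] object.
#' @return A validated `techtree`.
#' @examples
#' tr <- generate_tree(tree_gen_params(seed = 1))
#' tr
#' @export
generate_tree <- function(params = tree_gen_params()) {
  stopifnot(inherits(params, "tree_gen_params"))
  with_seed_or_stream(params$seed, generate_tree_impl(params))
}

generate_tree_impl <- function(params) {
  p <- params
  if (p$n_logs >= 1 && p$min_basic_log_closure > p$n_intermediate + 1) {
    stopf(paste0("infeasible: min_basic_log_closure = %d requires at least",
                 " %d intermediates, got %d"),
          p$min_basic_log_closure, p$min_basic_log_closure - 1,
          p$n_intermediate)
  }
  base_ids <- sprintf("b%d", seq_len(p$n_base))
  int_ids <- if (p$n_intermediate > 0) {
    sprintf("i%02d", seq_len(p$n_intermediate))
  } else character(0)
  log_ids <- if (p$n_logs > 0) sprintf("l%03d", seq_len(p$n_logs)) else
    character(0)

  used <- new.env(parent = emptyenv())
  recipes <- list()
  complexity <- stats::setNames(rep(0, p$n_base), base_ids)
  closure <- stats::setNames(rep(list(character(0)), p$n_base), base_ids)
  avail <- base_ids
  spine_len <- if (p$n_logs >= 1) p$min_basic_log_closure - 1L else 0L

  for (j in seq_along(int_ids)) {
    id <- int_ids[j]
    # weight towards complex items so depth accumulates
    w <- 1 + complexity[avail]
    force_in <- if (j >= 2 && j <= spine_len) int_ids[j - 1] else character(0)
    d <- draw_new_multiset(avail, w, p$max_inputs, used,
                           force_include = force_in)
    used[[d$key]] <- id
    recipes[[id]] <- d$inputs
    cl <- sort(unique(c(id, unlist(closure[unique(d$inputs)],
                                   use.names = FALSE))))
    closure[[id]] <- cl
    complexity[id] <- length(cl)
    avail <- c(avail, id)
  }

  unused_int <- int_ids # intermediates not yet inside any log's closure
  deep_ints <- int_ids[complexity[int_ids] >= p$min_basic_log_closure - 1]
  if (p$n_logs >= 1 && length(deep_ints) == 0L) {
    stopf("infeasible: no intermediate reaches complexity %d for basic logs",
          p$min_basic_log_closure - 1)
  }

  for (j in seq_along(log_ids)) {
    id <- log_ids[j]
    if (j <= p$n_basic_logs) {
      # basic log: anchored on a deep intermediate so its closure is at
      # least min_basic_log_closure
      anchor <- deep_ints[sample.int(length(deep_ints), 1L)]
      pool <- c(base_ids, int_ids)
      d <- draw_new_multiset(pool, 1 + complexity[pool], p$max_inputs, used,
                             force_include = anchor)
    } else {
      # refinement: one existing log plus intermediate items ("tools")
      prev <- log_ids[seq_len(j - 1L)]
      parent <- prev[sample.int(length(prev), 1L,
                                prob = 1 + complexity[prev])]
      force_in <- parent
      if (length(unused_int) > 0L && p$max_inputs >= 3L) {
        # cover not-yet-useful intermediates so that every intermediate
        # ends up in some log's closure
        force_in <- c(force_in,
                      unused_int[sample.int(length(unused_int), 1L)])
      }
      pool <- if (length(int_ids) > 0) int_ids else base_ids
      d <- draw_new_multiset(pool, 1 + complexity[pool], p$max_inputs, used,
                             force_include = force_in)
    }
    used[[d$key]] <- id
    recipes[[id]] <- d$inputs
    cl <- sort(unique(c(id, unlist(closure[unique(d$inputs)],
                                   use.names = FALSE))))
    closure[[id]] <- cl
    complexity[id] <- length(cl)
    unused_int <- setdiff(unused_int, cl)
  }

  if (p$n_logs >= 1 && length(unused_int) > 0L) {
    stopf("infeasible: %d intermediates end up in no log's closure",
          length(unused_int))
  }

  items <- data.frame(
    id = c(base_ids, int_ids, log_ids),
    kind = c(rep("base", p$n_base),
             rep("intermediate", p$n_intermediate),
             rep("log", p$n_logs)),
    name = c(base_ids, int_ids, log_ids),
    stringsAsFactors = FALSE)
  new_techtree(items, recipes, base_ids,
               basic_log_ids = log_ids[seq_len(p$n_basic_logs)],
               params = p, closures = closure)
}

#' Validate a technology tree against its structural invariants
#'
#' Checks every invariant a playable tree must satisfy: unique item ids,
#' exactly one recipe per non-base item and none for base resources,
#' recipe sizes within the workshop slot limit, globally unique recipe
#' input multisets, reachability of every item from the base resources
#' (which implies acyclicity of the requirement relation), usefulness of
#' every intermediate (member of at least one log's closure), and the
#' minimum closure size of every basic log.
#'
#' @param tree A `techtree`.
#' @return An object of class `tree_validation` with elements `valid`
#'   (logical) and `violations` (character vector, empty when valid).
#' @export
validate_tree <- function(tree) {
  v <- character(0)
  ids <- tree$items$id
  if (anyDuplicated(ids)) {
    v <- c(v, sprintf("duplicate item ids: %s",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (!all(tree$items$kind %in% c("base", "intermediate", "log"))) {
    v <- c(v, "unknown item kind present")
  }
  max_inputs <- if (!is.null(tree$params)) tree$params$max_inputs else 4L
  non_base <- setdiff(ids, tree$base_ids)
  missing_recipe <- setdiff(non_base, names(tree$recipes))
  if (length(missing_recipe) > 0) {
    v <- c(v, sprintf("recipe missing for non-base items: %s",
                      paste(missing_recipe, collapse = ", ")))
  }
  base_with_recipe <- intersect(tree$base_ids, names(tree$recipes))
  if (length(base_with_recipe) > 0) {
    v <- c(v, sprintf("base items with a recipe: %s",
                      paste(base_with_recipe, collapse = ", ")))
  }
  sizes <- lengths(tree$recipes)
  bad_size <- names(sizes)[sizes < 1 | sizes > max_inputs]
  if (length(bad_size) > 0) {
    v <- c(v, sprintf("recipe size outside 1..%d for: %s", max_inputs,
                      paste(bad_size, collapse = ", ")))
  }
  unknown_inputs <- setdiff(unique(unlist(tree$recipes)), ids)
  if (length(unknown_inputs) > 0) {
    v <- c(v, sprintf("recipes reference unknown items: %s",
                      paste(unknown_inputs, collapse = ", ")))
  }
  keys <- vapply(tree$recipes, multiset_key, character(1))
  if (anyDuplicated(keys)) {
    dup <- names(keys)[keys %in% keys[duplicated(keys)]]
    v <- c(v, sprintf("recipe uniqueness: outputs %s share an input multiset",
                      paste(dup, collapse = ", ")))
  }
  cls <- all_closures(tree, use_cache = FALSE)
  unreachable <- names(cls)[vapply(cls, is.null, logical(1))]
  unreachable <- setdiff(unreachable, tree$base_ids)
  if (length(unreachable) > 0) {
    v <- c(v, sprintf(
      "reachability: items not producible from base resources (cycle or gap): %s",
      paste(unreachable, collapse = ", ")))
  }
  log_ids <- tree_log_ids(tree)
  int_ids <- tree_intermediate_ids(tree)
  if (length(log_ids) > 0 && length(int_ids) > 0) {
    useful <- unique(unlist(cls[intersect(log_ids, setdiff(ids, unreachable))],
                            use.names = FALSE))
    orphans <- setdiff(int_ids, useful)
    if (length(orphans) > 0) {
      v <- c(v, sprintf("usefulness: intermediates in no log's closure: %s",
                        paste(orphans, collapse = ", ")))
    }
  }
  min_cl <- if (!is.null(tree$params)) tree$params$min_basic_log_closure else 8L
  for (b in tree$basic_log_ids) {
    cl <- cls[[b]]
    if (!is.null(cl) && length(cl) < min_cl) {
      v <- c(v, sprintf("basic log %s has closure %d < required %d",
                        b, length(cl), min_cl))
    }
  }
  structure(list(valid = length(v) == 0L, violations = v),
            class = "tree_validation")
}

#' @export
print.tree_validation <- function(x, ...) {
  if (x$valid) {
    cat("Tree valid: all structural invariants satisfied\n")
  } else {
    cat("Tree INVALID:\n")
    for (s in x$violations) cat(" -", s, "\n")
  }
  invisible(x)
}
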