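#' Canonicalize a workshop combination
#'
#' A workshop attempt drops 1 to 4 items (repetition allowed) into the
#' panel; the order of the slots never matters, so combinations are
#' multisets and are stored in canonical sorted order.  Any permutation of
#' the same items canonicalizes to the same combination.
#'
#' @param items Character vector of 1-4 item ids (repeats allowed).
#' @return The canonical combination: a sorted character vector of class
#'   `combination`.
#' @examples
#' canonicalize(c("b2", "b1"))  # "b1" "b2"
#' @export
canonicalize <- function(items) {
  items <- as.character(unclass(items))
  if (length(items) < 1L || length(items) > 4L) {
    stopf("a combination holds 1 to 4 items, got %d", length(items))
  }
  structure(sort(items), class = "combination")
}

#' Execute a workshop attempt
#'
#' An attempt succeeds when the canonical combination equals the input
#' multiset of some recipe; the recipe's output is produced.  Producing an
#' already-known item succeeds again (it simply adds nothing new to the
#' player's record).  Every item used must be available to the player;
#' base resources always are.
#'
#' @param tree A `techtree`.
#' @param available Character vector of item ids the player can use
#'   (base resources are implicitly included).
#' @param combination Items of the attempt (canonicalized internally).
#' @param recipe_index Optional prebuilt lookup from [recipe_index()];
#'   pass it in hot loops to avoid rebuilding.
#' @return A list with `success` (logical) and `produced` (item id, or
#'   `NULL` on failure).
#' @export
attempt <- function(tree, available, combination, recipe_index = NULL) {
  comb <- canonicalize(combination)
  usable <- c(tree$base_ids, available)
  missing <- setdiff(unique(comb), usable)
  if (length(missing) > 0) {
    stopf("items not available to this player: %s",
          paste(missing, collapse = ", "))
  }
  if (is.null(recipe_index)) recipe_index <- build_recipe_index(tree)
  out <- recipe_index[[multiset_key(comb)]]
  if (is.null(out)) list(success = FALSE, produced = NULL)
  else list(success = TRUE, produced = out)
}

#' Build a recipe lookup table for fast attempts
#'
#' @param tree A `techtree`.
#' @return An environment mapping canonical input-multiset keys to output
#'   item ids.
#' @export
build_recipe_index <- function(tree) {
  idx <- new.env(parent = emptyenv(), size = max(29L,
                                                 length(tree$recipes)))
  for (out in names(tree$recipes)) {
    idx[[multiset_key(tree$recipes[[out]])]] <- out
  }
  idx
}

#' Scoring parameters
#'
#' The totem score rewards both log value and log diversity: with the
#' default formula a totem of logs with values `v` scores
#' `sum(v) * (1 + beta * alpha)`, where `alpha` is the number of distinct
#' logs minus one (0, 1 or 2 for a three-slot totem) and `beta` is the
#' diversity weight (default 0.5, so full diversity doubles the sum).
#' A player's final score is the score of their best totem plus
#' `points_per_innovation` (default 15) for every distinct item they
#' produced themselves.
#'
#' The totem formula is pluggable: supply `totem_formula` as
#' `function(values, alpha, params)` returning points to replace the
#' default multiplicative form.
#'
#' @param points_per_innovation Points per produced innovation (default
#'   15).
#' @param diversity_weight The diversity multiplier weight `beta`
#'   (default 0.5).
#' @param totem_formula Optional replacement scoring function.
#' @return An object of class `score_params`.
#' @export
score_params <- function(points_per_innovation = 15, diversity_weight = 0.5,
                         totem_formula = NULL) {
  if (points_per_innovation <= 0) stopf("points_per_innovation must be > 0")
  structure(list(points_per_innovation = as.numeric(points_per_innovation),
                 diversity_weight = as.numeric(diversity_weight),
                 totem_formula = totem_formula),
            class = "score_params")
}

#' Score a totem
#'
#' @param log_values Named numeric vector, log id -> points.
#' @param totem Character vector of 1-3 log ids (a multiset).
#' @param params A [score_params()] object.
#' @return The totem score in points.
#' @examples
#' totem_score(c(A = 50), "A")                      # 50
#' totem_score(c(A = 10, B = 20, C = 30), c("A", "B", "C")) # 120
#' @export
totem_score <- function(log_values, totem, params = score_params()) {
  totem <- as.character(unclass(totem))
  if (length(totem) < 1L || length(totem) > 4L - 1L) {
    stopf("a totem holds 1 to 3 logs, got %d", length(totem))
  }
  unknown <- setdiff(unique(totem), names(log_values))
  if (length(unknown) > 0) {
    stopf("logs without an assigned value: %s",
          paste(unknown, collapse = ", "))
  }
  v <- log_values[totem]
  alpha <- length(unique(totem)) - 1L
  if (!is.null(params$totem_formula)) {
    params$totem_formula(v, alpha, params)
  } else {
    sum(v) * (1 + params$diversity_weight * alpha)
  }
}

#' Final score of a player
#'
#' Best-totem points (0 when no totem was built) plus
#' `points_per_innovation` for each distinct item the player produced.
#'
#' @param n_innovations Number of distinct items personally produced.
#' @param best_totem_points Score of the best totem built, or 0.
#' @param params A [score_params()] object.
#' @return Final score in points.
#' @export
final_score <- function(n_innovations, best_totem_points = 0,
                        params = score_params()) {
  best_totem_points + params$points_per_innovation * n_innovations
}

#' Best totem over a set of available logs
#'
#' Exhaustively maximizes the totem score over every multiset of 1-3 logs
#' drawn from `available_logs`.  Ties break deterministically towards the
#' canonically smallest totem (sorted id sequence, shorter first).
#'
#' @param log_values Named numeric vector, log id -> points.
#' @param available_logs Character vector of log ids the player can place.
#' @param params A [score_params()] object.
#' @return `NULL` when no log is available, otherwise a list with `totem`
#'   (canonical log multiset) and `points`.
#' @export
best_totem <- function(log_values, available_logs, params = score_params()) {
  logs <- sort(unique(as.character(available_logs)))
  if (length(logs) == 0L) return(NULL)
  unknown <- setdiff(logs, names(log_values))
  if (length(unknown) > 0) {
    stopf("logs without an assigned value: %s",
          paste(unknown, collapse = ", "))
  }
  designs <- enumerate_multisets(logs, 3L)
  scores <- vapply(designs, function(d) totem_score(log_values, d, params),
                   numeric(1))
  best <- max(scores)
  cand <- designs[scores == best]
  keys <- vapply(cand, function(d) {
    sprintf("%d|%s", length(d), paste(d, collapse = "|"))
  }, character(1))
  list(totem = cand[[order(keys)[1]]], points = best)
}
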