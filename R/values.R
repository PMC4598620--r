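#' Parameters for log point-value assignment
#'
#' Every log carries a unique point value drawn at random from an integer
#' interval determined by its complexity tier (its innovation-closure
#' size).  Tier intervals are disjoint and strictly increasing with
#' complexity, so a more complex log is always worth more, while two logs
#' of equal complexity get distinct values from the same interval.  The
#' least valuable log is always worth exactly `value_floor` points.
#'
#' By default the tier intervals are consecutive integer ranges of equal
#' per-log granularity spanning `[value_floor, value_ceiling]`.  The
#' default ceiling of 1235 is chosen so that, on a default-sized tree, the
#' best three-distinct-log totem scores near the original game's 7,410
#' ceiling (three top-value logs with the full diversity multiplier give
#' `2 * 3 * 1235 = 7410`).  Explicit `tiers` override the automatic
#' spacing: a named list mapping closure size to `c(lo, hi)` half-open
#' integer intervals `[lo, hi)`.
#'
#' @param value_floor Minimum (and guaranteed attained) log value
#'   in points; default 50.
#' @param value_ceiling Upper bound of the automatic tier layout; default
#'   1235 points.
#' @param tiers Optional explicit tier map (named list, names are closure
#'   sizes, values are `c(lo, hi)` with `lo < hi`).
#' @param seed Optional integer seed for the random draw.
#' @return An object of class `log_value_params`.
#' @export
log_value_params <- function(value_floor = 50, value_ceiling = 1235,
                             tiers = NULL, seed = NULL) {
  if (value_floor < 1) stopf("value_floor must be positive")
  if (is.null(tiers) && value_ceiling <= value_floor) {
    stopf("value_ceiling must exceed value_floor")
  }
  structure(list(value_floor = as.numeric(value_floor),
                 value_ceiling = as.numeric(value_ceiling),
                 tiers = tiers,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "log_value_params")
}

#' Assign point values to the logs of a tree
#'
#' Draws one distinct integer value per log from its complexity tier's
#' interval (see [log_value_params()]).  Guarantees: values are pairwise
#' distinct; a log of strictly greater complexity always has a strictly
#' greater value; the minimum over all logs equals `value_floor`; the
#' same seed reproduces the same mapping.
#'
#' @param tree A valid `techtree` with at least one log.
#' @param params A [log_value_params()] object.
#' @return Named numeric vector, log id -> points.
#' @examples
#' tr <- generate_tree(tree_gen_params(seed = 1))
#' vals <- assign_log_values(tr, log_value_params(seed = 1))
#' min(vals) # 50
#' @export
assign_log_values <- function(tree, params = log_value_params()) {
  stopifnot(inherits(params, "log_value_params"))
  log_ids <- tree_log_ids(tree)
  if (length(log_ids) == 0L) stopf("tree has no logs to value")
  cls <- all_closures(tree)
  comp <- vapply(log_ids, function(id) length(cls[[id]]), integer(1))
  with_seed_or_stream(params$seed,
                      assign_log_values_impl(log_ids, comp, params))
}

assign_log_values_impl <- function(log_ids, comp, params) {
  tiers <- sort(unique(comp))
  counts <- vapply(tiers, function(tt) sum(comp == tt), integer(1))
  if (is.null(params$tiers)) {
    span <- params$value_ceiling - params$value_floor + 1
    g <- max(1, floor(span / length(log_ids)))
    hi_needed <- params$value_floor + g * length(log_ids) - 1
    if (hi_needed > params$value_ceiling) {
      stopf(paste0("value interval [%g, %g] too narrow to host %d distinct",
                   " log values"),
            params$value_floor, params$value_ceiling, length(log_ids))
    }
    cum <- c(0, cumsum(counts))
    lo <- params$value_floor + g * cum[-length(cum)]
    hi <- params$value_floor + g * cum[-1] # half-open [lo, hi)
  } else {
    tn <- as.numeric(names(params$tiers))
    if (!all(tiers %in% tn)) {
      stopf("explicit tiers missing closure sizes: %s",
            paste(setdiff(tiers, tn), collapse = ", "))
    }
    iv <- params$tiers[match(tiers, tn)]
    lo <- vapply(iv, `[`, numeric(1), 1)
    hi <- vapply(iv, `[`, numeric(1), 2)
    if (any(hi <= lo)) stopf("tier intervals must satisfy lo < hi")
    if (any(diff(lo) <= 0) || any(lo[-1] < hi[-length(hi)])) {
      stopf("tier intervals must be disjoint and increasing with complexity")
    }
    if (any(hi - lo < counts)) {
      bad <- which(hi - lo < counts)[1]
      stopf("tier %s interval [%g, %g) too narrow for %d distinct values",
            tiers[bad], lo[bad], hi[bad], counts[bad])
    }
    if (lo[1] != params$value_floor) {
      stopf("lowest tier interval must start at value_floor (%g)",
            params$value_floor)
    }
  }
  values <- numeric(0)
  for (t in seq_along(tiers)) {
    pool <- seq.int(lo[t], hi[t] - 1)
    n <- counts[t]
    pick <- if (t == 1L) {
      # force the floor so the cheapest log is worth exactly value_floor
      if (n == 1L) pool[1] else
        c(pool[1], pool[-1][sample.int(length(pool) - 1L, n - 1L)])
    } else {
      pool[sample.int(length(pool), n)]
    }
    members <- log_ids[comp == tiers[t]]
    pick <- pick[sample.int(length(pick))] # random pairing value -> log
    values <- c(values, stats::setNames(pick, members))
  }
  values[log_ids]
}
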