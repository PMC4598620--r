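#' Count distinct workshop combinations available from a pool of items
#'
#' A workshop attempt is an unordered selection of `1` to `max_slots` items
#' with repetition allowed, i.e. a multiset.  The number of distinct
#' multisets of size `k` drawn from `n` item types is the multiset
#' coefficient `choose(n + k - 1, k)`, so the number of distinct attempts is
#' the sum of those coefficients over the allowed sizes.  With a pool of six
#' items and four slots this gives 209 combinations; a pool of ten gives
#' 1000 — the combinatorial explosion that makes undirected search
#' progressively harder as innovations accumulate.
#'
#' @param pool_size Number of distinct item types available (positive
#'   integer).
#' @param max_slots Maximum selection size (positive integer; the workshop
#'   holds 4).
#' @return The number of distinct unordered combinations, as a double.
#' @examples
#' count_reachable_combinations(6, 4)  # 209
#' count_reachable_combinations(10, 4) # 1000
#' @export
count_reachable_combinations <- function(pool_size, max_slots) {
  check_count_args(pool_size, max_slots)
  k <- seq_len(max_slots)
  sum(choose(pool_size + k - 1, k))
}

#' Count distinct totem designs over a set of log types
#'
#' A totem is an unordered multiset of one to `slots` logs (the totem panel
#' holds three).  The count is the same multiset-coefficient sum as for
#' workshop combinations: 115 log types yield 266,915 distinct designs.
#'
#' @param n_log_types Number of distinct log types (positive integer).
#' @param slots Totem panel size (positive integer).
#' @return The number of distinct totem designs, as a double.
#' @examples
#' count_totem_designs(115, 3) # 266915
#' @export
count_totem_designs <- function(n_log_types, slots) {
  check_count_args(n_log_types, slots)
  k <- seq_len(slots)
  sum(choose(n_log_types + k - 1, k))
}

check_count_args <- function(n, k) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != floor(n)) {
    stopf("pool/type count must be a single positive integer, got %s",
          deparse(n))
  }
  if (length(k) != 1L || !is.finite(k) || k < 1 || k != floor(k)) {
    stopf("slot count must be a single positive integer, got %s", deparse(k))
  }
  invisible(TRUE)
}

# All multisets of sizes 1..max_size over `ids`, as a list of sorted
# character vectors.  Used by the exhaustive best-totem search and the
# exact fallback of the unique-attempt sampler; cost grows as the multiset
# coefficient, so callers guard the pool size.
enumerate_multisets <- function(ids, max_size) {
  ids <- sort(ids)
  n <- length(ids)
  out <- vector("list", 0L)
  for (k in seq_len(max_size)) {
    idx <- utils::combn(n + k - 1, k)
    # stars-and-bars bijection: subtract 0..k-1 to map combinations
    # without repetition onto non-decreasing k-tuples with repetition
    idx <- idx - (seq_len(k) - 1L)
    out <- c(out, lapply(seq_len(ncol(idx)), function(j) ids[idx[, j]]))
  }
  out
}
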