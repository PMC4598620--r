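# Independent oracles used to check the package's operations.  These are
# deliberately naive: exhaustive enumeration and fixed-point sweeps,
# sharing no code with the implementation they check.

# All unordered multisets of sizes 1..max_size over `ids`, by enumerating
# every ordered tuple and deduplicating the sorted forms.
oracle_enumerate_multisets <- function(ids, max_size) {
  keys <- character(0)
  for (k in seq_len(max_size)) {
    g <- do.call(expand.grid,
                 c(rep(list(ids), k), stringsAsFactors = FALSE))
    sorted <- apply(as.matrix(g), 1, function(r) {
      paste(sort(r), collapse = "|")
    })
    keys <- c(keys, unique(sorted))
  }
  unique(keys)
}

oracle_count_multisets <- function(n_types, max_size) {
  length(oracle_enumerate_multisets(paste0("x", sprintf("%03d", 1:n_types)),
                                    max_size))
}

# Forward-production closure oracle: repeatedly apply every executable
# recipe starting from the base set; an item's closure is found by a
# backward union over the recipe of each item in its own closure.
oracle_closure <- function(recipes, base_ids, item_id) {
  if (item_id %in% base_ids) return(character(0))
  # producibility check first
  have <- base_ids
  repeat {
    new <- names(recipes)[vapply(names(recipes), function(o) {
      !(o %in% have) && all(recipes[[o]] %in% have)
    }, logical(1))]
    if (length(new) == 0) break
    have <- c(have, new)
  }
  stopifnot(item_id %in% have)
  need <- item_id
  repeat {
    more <- setdiff(setdiff(unique(unlist(recipes[need])), base_ids), need)
    if (length(more) == 0) break
    need <- c(need, more)
  }
  sort(need)
}

# Exhaustive best-totem oracle: three nested loops over available logs.
oracle_best_totem <- function(values, logs, beta = 0.5) {
  logs <- sort(unique(logs))
  best <- -Inf
  for (i in seq_along(logs)) {
    for (j in c(0L, seq(i, length(logs)))) {
      for (k in if (j == 0L) 0L else c(0L, seq(j, length(logs)))) {
        totem <- logs[c(i, j, k)[c(i, j, k) > 0]]
        alpha <- length(unique(totem)) - 1
        s <- sum(values[totem]) * (1 + beta * alpha)
        if (s > best) best <- s
      }
    }
  }
  best
}
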