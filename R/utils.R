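#' @keywords internal
"_PACKAGE"

# Run `expr` under `seed` when seed is non-NULL, otherwise use the current
# RNG stream.  Centralises the package-wide seeding convention: every
# user-facing stochastic function takes a `seed` argument and is bit-
# reproducible when it is given.
with_seed_or_stream <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

#' Derive a per-replicate seed from a master seed
#'
#' Replicate `i` of a run with master seed `s` uses the seed
#' `(s * 48271 + i * 16807) mod (2^31 - 2) + 1`, a fixed affine hash that
#' keeps replicate streams distinct and the derived seed inside the range
#' of a 32-bit R integer.
#'
#' @param master_seed Integer master seed.
#' @param index Positive integer replicate index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, index) {
  m <- 2147483646 # 2^31 - 2
  x <- (as.double(master_seed) %% m) * 48271 + as.double(index) * 16807
  as.integer(x %% m + 1)
}

# Canonical string key of a multiset of item ids (sorted, pipe-joined).
# Ids never contain "|".
multiset_key <- function(ids) {
  paste(sort(ids), collapse = "|")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
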