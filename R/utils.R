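# Internal helpers: error conditions, seed derivation, edge keys.

stop_kinnet <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "kinnet_error")))
}

#' Derive a replicate seed from a master seed
#'
#' Counter-based derivation so that replicate `index` of a run with master
#' seed `seed` is reproducible in isolation. Always returns a positive
#' integer below 2^31 - 1.
#'
#' @param seed Master seed (integer).
#' @param index Counter (replicate index, attempt number, ...).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(index), length(index) == 1L)
  m <- 2147483647  # 2^31 - 1, Mersenne prime; arithmetic exact in doubles
  x <- (abs(as.numeric(seed)) %% m) + 1
  x <- (x * 48271) %% m
  x <- (x + (abs(as.numeric(index)) %% m) * 16807) %% m
  x <- (x * 69621) %% m
  as.integer(x + 1)
}

# Canonical unordered pair key "min max" used to deduplicate edges.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b))
}

# Set the RNG if a seed is given; no-op otherwise.
maybe_set_seed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L)
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
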