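# internal helpers: argument checking and seed handling

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    abort(sprintf("`%s` must be supplied.", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)))
  }
  invisible(x)
}

# Split one user-facing seed into independent sub-stream seeds.
# Deterministic: sub-seeds are drawn once from a generator seeded with the
# master seed, all below 2^31. Sub-stream k of a given master seed is stable
# regardless of how many sub-streams are requested.
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed) %% .Machine$integer.max,
                   sample.int(.Machine$integer.max - 1L, n))
}

# half-open interval membership [lo, hi)
`%inco%` <- function(x, bounds) x >= bounds[1] & x < bounds[2]
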