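# Internal helpers shared across modules.

# Run `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards. Keeps every simulate_* call self-contained.
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Canonical form for label comparison: trim whitespace, fold case.
norm_label <- function(x) tolower(trimws(as.character(x)))

# Named probability vector: validate, normalise to sum 1.
norm_probs <- function(p, what) {
  if (is.null(names(p)) || any(!nzchar(names(p)))) {
    stop(sprintf("'%s' must be a named probability vector", what), call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0) || sum(p) <= 0) {
    stop(sprintf("'%s' must be non-negative with positive sum", what), call. = FALSE)
  }
  p / sum(p)
}

sample_cat <- function(p, n) {
  names(p)[sample.int(length(p), n, replace = TRUE, prob = p)]
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
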