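# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All user-facing randomness in the
# package funnels through this so that seeds are explicit arguments, never
# global state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  code
}

# Derive a stream of child seeds from one parent seed, staying inside the
# 32-bit integer range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
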