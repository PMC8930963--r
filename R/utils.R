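# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators behave as pure functions of their arguments.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministically derive a child seed from a parent seed and an index, so
# that one user-facing seed drives many independent random streams.
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + 92821 * as.double(i)) %% 2147483587
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_invalid("`%s` must be a single positive finite number", name)
  }
}

# Ordered day labels used throughout (d0 = familiarization, d17 = retention).
DAY_LEVELS <- c("d0", "d1", "d2", "d3", "d4", "d5", "d17")

day_number <- function(day) as.numeric(sub("^d", "", day))
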