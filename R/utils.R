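# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All user-facing stochastic operations funnel
# through this so identical (inputs, seed) give identical output without
# clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stream label, staying below
# 2^31 so it remains a valid R integer.
child_seed <- function(seed, stream) {
  x <- sum(utf8ToInt(as.character(stream))) * 10177L
  (as.integer(seed) %% 1000003L) * 2039L + x %% 1000003L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_config("%s is missing column(s): %s", what,
                paste(missing, collapse = ", "))
  }
  invisible(df)
}
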