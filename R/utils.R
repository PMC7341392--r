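# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Derived sub-seed kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + as.numeric(k)) %% 2147483646 + 1)
}

stop_if_not_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= 0) || (!strict && x < 0))
    stop(sprintf("'%s' must be a finite %s scalar", name,
                 if (strict) "strictly positive" else "non-negative"),
         call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
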