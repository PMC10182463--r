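# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL means "use current RNG".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a sub-stream seed from a user seed; kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((abs(as.numeric(seed)) * 1009 + offset) %% 2147483647)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Pearson correlation that refuses to return NaN on degenerate input.
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) stop("Pearson correlation needs at least 2 paired values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson correlation undefined: zero variance in input", call. = FALSE)
  stats::cor(x, y)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}
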