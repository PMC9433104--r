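# Run `expr` under a deterministic RNG state without disturbing the caller's.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Draw `n` counts from a "count distribution" argument: a single integer
# (degenerate), a named probability vector (names = counts), or a function(n).
draw_counts <- function(spec, n) {
  if (is.function(spec)) {
    out <- spec(n)
  } else if (length(spec) == 1L && is.null(names(spec))) {
    out <- rep(as.integer(spec), n)
  } else {
    if (is.null(names(spec))) stop("count distribution vector must be named")
    out <- sample(as.integer(names(spec)), n, replace = TRUE,
                  prob = as.numeric(spec))
  }
  out <- as.integer(out)
  if (anyNA(out) || any(out < 0)) stop("invalid counts drawn")
  out
}

# Draw `n` positive durations (minutes) from a "distribution" argument: a
# single number (mean of a gamma with shape 2) or a function(n).
draw_duration <- function(spec, n, min_value = 0) {
  if (n == 0L) return(numeric(0))
  out <- if (is.function(spec)) spec(n)
         else stats::rgamma(n, shape = 2, scale = as.numeric(spec) / 2)
  pmax(out, min_value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
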