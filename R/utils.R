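# Shared internal helpers: seed handling, argument checks, run-length tools.

#' Derive a stream of child seeds from one session seed
#'
#' All generators in the package draw their randomness from a single session
#' seed through this splitter: the parent seed seeds R's RNG once and `n`
#' integer child seeds are drawn. Child seeds are strictly below 2^31 so they
#' are always representable as R integers.
#'
#' @param seed integer scalar parent seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
split_seed <- function(seed, n = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. `seed = NULL` leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# interval helpers ----------------------------------------------------------

check_interval <- function(x, name = deparse(substitute(x))) {
  if (!(is.numeric(x) && length(x) == 2L && all(is.finite(x)) && x[1] < x[2]))
    stop(sprintf("'%s' must be a finite (start, end) pair with start < end",
                 name), call. = FALSE)
  invisible(x)
}

# intersection of a list of (start, end) intervals; NULL if empty
intersect_intervals <- function(ints) {
  lo <- max(vapply(ints, `[`, numeric(1), 1L))
  hi <- min(vapply(ints, `[`, numeric(1), 2L))
  if (lo >= hi) NULL else c(lo, hi)
}

# maximal runs of TRUE in a logical vector -> list of c(first, last) indices
true_runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(i) c(starts[i], ends[i]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
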