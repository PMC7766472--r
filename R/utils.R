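# Internal helpers shared across the package.

#' @keywords internal
#' @importFrom stats coef predict simulate
"_PACKAGE"

## Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
## Used everywhere a `seed` argument is offered so seeded calls never disturb
## the session RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Bipolar vector check: every entry exactly +1 or -1.
is_bipolar <- function(x) {
  is.numeric(x) && length(x) > 0L && all(x == 1 | x == -1)
}

assert_bipolar <- function(x, what = "vector") {
  if (!is_bipolar(x)) {
    stop(sprintf("%s must be bipolar: every entry exactly +1 or -1", what),
         call. = FALSE)
  }
  invisible(x)
}

## Sign threshold with the keep-previous tie rule: strictly positive fields go
## high, strictly negative go low, an exactly-zero field keeps the prior state.
sign_threshold <- function(u, previous) {
  out <- previous
  out[u > 0] <- 1
  out[u < 0] <- -1
  out
}
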