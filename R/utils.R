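#' @keywords internal
"_PACKAGE"

## Run code with a local RNG seed, restoring global .Random.seed afterwards.
## All stochastic entry points route their randomness through this so that a
## single seed argument fully determines the output and no hidden global
## state leaks between calls.
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
    set.seed(as.integer(seed))
  }
  force(code)
}

## population standardization (ddof = 0); errors on zero variance
standardize0 <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stop("cannot standardize: zero variance")
  (x - m) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
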