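#' @keywords internal
"_PACKAGE"

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
## seed = NULL means "use the current RNG stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministically derive a sub-seed for pipeline stage `k` from a master
## seed, staying inside 32-bit integer range.
stage_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 101L + k * 9973L) %% 2147483587)
}

## Stochastic rounding: floor plus a Bernoulli draw on the fractional part,
## so that E[round(x)] = x and integer inputs pass through unchanged.
stochastic_round <- function(x) {
  f <- floor(x)
  r <- x - f
  add <- stats::runif(length(x)) < r
  out <- f + as.numeric(add)
  dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}

## Symmetry check with tolerance, used by matrix validators.
is_symmetric <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
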