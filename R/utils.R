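#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{code} with the global RNG seeded to \code{seed}, then restores
#' whatever RNG state existed before the call, so library functions that take
#' a \code{seed} argument are deterministic without clobbering the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector.
#' @return \code{log(sum(exp(x)))} computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)  # all -Inf (or an Inf, which propagates)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix, returning one value per row.
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  bad <- !is.finite(m)
  out <- m + log(rowSums(exp(x - m)))
  out[bad] <- m[bad]
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a
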