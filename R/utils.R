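# Internal helpers shared across modules.

# Deterministic sub-seed for a named random substream, derived from one master
# seed. Keeps every stochastic draw (schedule, loadings, noise, ...)
# independently reproducible. Result stays inside the 32-bit integer range.
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((abs(master) + h) %% .Machine$integer.max)
}

with_substream <- function(master, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(master, name))
  force(code)
}

# Moore-Penrose pseudoinverse via SVD. Singular values below tol * max are
# treated as zero (stability for near-duplicate units).
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, .Machine$double.eps)
  if (!any(keep)) {
    return(matrix(0, ncol(A), nrow(A)))
  }
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Trace of the covariance of a score matrix = sum of column variances.
trace_var <- function(scores) {
  if (nrow(scores) < 2L) {
    stop("need at least two rows to compute a variance", call. = FALSE)
  }
  sum(apply(scores, 2L, var))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

abort_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
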