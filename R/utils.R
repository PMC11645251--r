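# Internal numerical helpers shared across the package.

#' @importFrom stats rnorm rbeta rmultinom runif dbeta optim sd t.test
#'   p.adjust qlogis plogis setNames ks.test ecdf quantile rbinom
#' @importFrom rlang %||% .data
NULL

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp of a matrix (max.col is the fast row-max path).
row_logsumexp <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  out <- m + log(rowSums(exp(x - m)))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

# Evaluate an expression with a locally-set RNG seed; NULL leaves the
# global stream untouched.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_probability_vector <- function(p, name = deparse(substitute(p)),
                                      tol = 1e-8) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stopf("'%s' must be a non-negative finite vector", name)
  }
  if (abs(sum(p) - 1) > tol) {
    stopf("'%s' must sum to 1 (got %.10f)", name, sum(p))
  }
  invisible(p)
}

# Floor a probability vector away from zero and renormalize; used inside
# log terms where a structurally-zero proportion would yield -Inf.
floor_simplex <- function(p, eps = 1e-12) {
  if (all(p >= eps)) return(p)
  p <- pmax(p, eps)
  p / sum(p)
}
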