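# Direct marginal-likelihood estimator: the per-sample integral over the
# latent mixing proportion is approximated by Gauss-Legendre quadrature on
# (0, 1) and the objective is maximized by block-coordinate Nelder-Mead
# (other-location composition block, then link-coefficient block).

# Cache Gauss-Legendre nodes/weights on [0, 1] per node count.
.gl_cache <- new.env(parent = emptyenv())
gl_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    .gl_cache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  }
  .gl_cache[[key]]
}


# Fast beta-shape computation (matrix in, no tibble) shared by the fitters.
# The precision linear predictor is capped so exp() cannot overflow when an
# optimizer explores extreme coefficients; shapes are kept strictly positive.
beta_shapes <- function(X, beta0, beta, gamma0, gamma) {
  d <- ncol(X)
  eta_mu  <- beta0  + if (d) drop(X %*% beta)  else 0
  eta_phi <- gamma0 + if (d) drop(X %*% gamma) else 0
  mu  <- stats::plogis(rep_len(eta_mu, nrow(X)))
  phi <- exp(pmin(pmax(rep_len(eta_phi, nrow(X)), -18.5), 18.5))  # ~[1e-8,1e8]
  list(a1 = pmax(mu * phi, 1e-12), a2 = pmax((1 - mu) * phi, 1e-12))
}

# Precompute everything reusable for repeated marginal log-likelihood
# evaluations on one dataset; returns function(p_o, beta0, beta, gamma0,
# gamma) -> per-sample log-likelihood vector.
#
# Two quadrature schemes share the Gauss-Legendre rule on [0, 1]:
#  * "beta_cdf" (default): each sample's integral is transformed with
#    u = F(pi; a1_i, a2_i), the beta CDF, so the integrand becomes the
#    multinomial factor at pi = F^{-1}(u) and the beta density integrates
#    exactly. This is robust to the endpoint singularities that arise
#    whenever a shape parameter is below 1 (the common case at moderate
#    precision phi), and makes the p_r = p_o reduction to the multinomial
#    likelihood exact. The transformed integrand still loses smoothness at
#    the endpoints for shapes below 1, so the public marginal_loglik()
#    doubles the node count in that regime; the fitting engines use the
#    base rule, whose residual error (~1e-5 in the objective) is far below
#    the optimizer's stopping noise.
#  * "legendre": affine-mapped nodes applied directly to pi, with the beta
#    log-density added to the node integrand. Cheaper (nodes shared across
#    samples) but inaccurate for singular shapes.
# Quantities are memoized per block: the node positions (and shapes) depend
# only on the link coefficients; under "legendre" the multinomial node
# matrix depends only on p_o.
marginal_loglik_engine <- function(Y, X, p_r, n_quad, floor,
                                   scheme = "beta_cdf") {
  gl <- gl_nodes(n_quad)
  nodes <- gl$x; logw <- log(gl$w)
  tY <- t(Y)                                   # S x G
  const <- lgamma(colSums(Y) + 1) - colSums(lgamma(Y + 1))
  S <- ncol(Y); Q <- n_quad
  logw_mat <- matrix(logw, S, Q, byrow = TRUE)
  last_coefs <- NULL; last_bl <- NULL; last_PI <- NULL; last_tY_rep <- NULL
  last_po <- NULL; last_mult <- NULL
  idx <- rep(seq_len(S), times = Q)
  floor_P <- function(P) {
    if (floor > 0 && any(P < floor)) {
      P <- pmax(P, floor)
      P <- P / rowSums(P)
    }
    P
  }
  if (scheme == "beta_cdf") {
    function(p_o, beta0, beta, gamma0, gamma) {
      coefs <- c(beta0, beta, gamma0, gamma)
      if (is.null(last_coefs) || !identical(coefs, last_coefs)) {
        sh <- beta_shapes(X, beta0, beta, gamma0, gamma)
        # clamp absurd shapes proposed by the optimizer; qbeta is unstable
        # beyond these and the likelihood there is not competitive anyway
        a1 <- pmin(pmax(sh$a1, 1e-8), 1e8)
        a2 <- pmin(pmax(sh$a2, 1e-8), 1e8)
        # S x Q per-sample nodes pi_iq = F^{-1}(u_q; a1_i, a2_i)
        PI <- suppressWarnings(stats::qbeta(rep(nodes, each = S), a1, a2))
        bad <- !is.finite(PI)
        if (any(bad)) {
          mu_rep <- rep_len(a1 / (a1 + a2), length(PI))
          PI[bad] <- mu_rep[bad]
        }
        last_PI <<- pmin(pmax(PI, 1e-300), 1 - 1e-16)
        if (is.null(last_tY_rep)) last_tY_rep <<- tY[idx, , drop = FALSE]
        last_coefs <<- coefs
      }
      P <- floor_P(outer(last_PI, p_r) + outer(1 - last_PI, p_o))  # (S*Q) x G
      mult <- matrix(rowSums(last_tY_rep * log(P)), S, Q)
      const + row_logsumexp(mult + logw_mat)
    }
  } else {
    nodes_rep <- rep(nodes, each = S)
    function(p_o, beta0, beta, gamma0, gamma) {
      if (is.null(last_po) || !identical(p_o, last_po)) {
        P <- floor_P(outer(nodes, p_r) + outer(1 - nodes, p_o))  # Q x G
        last_mult <<- tY %*% t(log(P))                           # S x Q
        last_po <<- p_o
      }
      coefs <- c(beta0, beta, gamma0, gamma)
      if (is.null(last_coefs) || !identical(coefs, last_coefs)) {
        sh <- beta_shapes(X, beta0, beta, gamma0, gamma)
        last_bl <<- matrix(dbeta(nodes_rep, sh$a1, sh$a2, log = TRUE),
                           nrow = S)
        last_coefs <<- coefs
      }
      const + row_logsumexp(last_mult + last_bl + logw_mat)
    }
  }
}

#' Marginal log-likelihood of the stool counts
#'
#' For each stool sample the joint density of counts and mixing proportion is
#' integrated over \eqn{\pi_i \in (0,1)} by Gauss-Legendre quadrature
#' (affine-mapped nodes), with the quadrature sum taken in log space via
#' log-sum-exp; the function returns the sum over samples. When some sample's
#' integrand underflows to zero at every node the result is `-Inf` and the
#' offending samples are reported in the `"bad_samples"` attribute — the
#' regime in which the EM estimator ([fit_em()]) remains usable.
#'
#' @param theta A [mixture_theta()]; its `p_r` is the plug-in reference
#'   estimate.
#' @param stool Taxa-by-samples count matrix of stool samples.
#' @param X Samples-by-covariates matrix (or `NULL` for intercept-only).
#' @param n_quad Base number of quadrature nodes (default 30). Under the
#'   `"beta_cdf"` scheme the count is doubled automatically when any
#'   sample's beta shapes fall below 1, where the transformed integrand
#'   converges more slowly.
#' @param floor Floor applied to mixture proportions inside logs (default 0).
#' @param scheme Quadrature scheme: `"beta_cdf"` (default) transforms each
#'   sample's integral by its beta CDF before applying the Gauss-Legendre
#'   rule, which integrates the beta factor exactly and tolerates shape
#'   parameters below 1; `"legendre"` applies the affine-mapped rule to
#'   \eqn{\pi} directly.
#' @return The scalar log-likelihood (possibly `-Inf`).
#' @export
marginal_loglik <- function(theta, stool, X = NULL, n_quad = 30, floor = 0,
                            scheme = c("beta_cdf", "legendre")) {
  scheme <- match.arg(scheme)
  Y <- as_count_matrix(stool)
  X <- as_covariate_matrix(X, ncol(Y))
  if (length(theta$p_r) != nrow(Y)) {
    stopf("theta has %d taxa but stool has %d", length(theta$p_r), nrow(Y))
  }
  if (ncol(X) != length(theta$beta)) {
    stopf("covariate dimension %d does not match coefficient length %d",
          ncol(X), length(theta$beta))
  }
  if (scheme == "beta_cdf") {
    sh <- beta_shapes(X, theta$beta0, theta$beta, theta$gamma0, theta$gamma)
    if (min(sh$a1, sh$a2) < 1) n_quad <- 2L * n_quad
  }
  engine <- marginal_loglik_engine(Y, X, theta$p_r, n_quad, floor, scheme)
  ll <- engine(theta$p_o, theta$beta0, theta$beta, theta$gamma0, theta$gamma)
  out <- sum(ll)
  if (!is.finite(out)) {
    attr(out, "bad_samples") <- colnames(Y)[!is.finite(ll)]
  }
  out
}

#' Fit the mixture model by direct marginal maximum likelihood
#'
#' Block-coordinate ascent on the quadrature-approximated marginal
#' log-likelihood: holding the link coefficients fixed, the other-location
#' composition is updated through its softmax parameterization (the last
#' softmax coordinate is pinned at 0 to remove the shift direction); then,
#' holding the composition fixed, the four-plus link coefficients are
#' updated. Both inner maximizations use Nelder-Mead. The reference
#' composition `p_hat_r` stays fixed at its plug-in value throughout.
#' Iteration stops when the objective changes by at most `tol` between
#' consecutive outer iterations, or after `max_outer` iterations. If a
#' heuristic inner step would decrease the objective the previous block
#' value is kept, so the trace is non-decreasing.
#'
#' @param stool Taxa-by-samples count matrix of stool samples.
#' @param X Samples-by-covariates matrix (or `NULL`).
#' @param p_hat_r Reference composition (e.g. from [estimate_p_r()]).
#' @param n_quad Quadrature nodes (default 30).
#' @param max_outer Maximum outer iterations (default 50).
#' @param tol Convergence threshold on the objective change (default 0.001).
#' @param inner_maxit,inner_reltol Nelder-Mead budget per block (defaults
#'   2000 evaluations, relative tolerance 1e-6).
#' @param floor Proportion floor inside logs (default 1e-12).
#' @param scheme Quadrature scheme, as in [marginal_loglik()].
#' @param init Optional list with elements `u` (length `G`, softmax scale)
#'   and/or `coefs` (`c(beta0, beta, gamma0, gamma)`) overriding the default
#'   initialization (log mean stool proportions; zeros).
#'
#' @return An object of class `demix_fit` with elements `theta_hat`,
#'   `loglik`, `loglik_trace`, `converged`, `n_outer`, `method = "demix1"`.
#' @export
#'
#' @examples
#' sim <- simulate_dataset(sim_design(G = 5, S = 30, S_r = 30, N = 500),
#'                         seed = 1)
#' fit <- fit_demix1(sim$stool, sim$covariates, estimate_p_r(sim$rectum),
#'                   max_outer = 3)
#' tidy(fit)
fit_demix1 <- function(stool, X = NULL, p_hat_r, n_quad = 30, max_outer = 50,
                       tol = 0.001, inner_maxit = 2000, inner_reltol = 1e-6,
                       floor = 1e-12, init = NULL,
                       scheme = c("beta_cdf", "legendre")) {
  scheme <- match.arg(scheme)
  Y <- as_count_matrix(stool)
  X <- as_covariate_matrix(X, ncol(Y))
  assert_probability_vector(p_hat_r, "p_hat_r")
  G <- nrow(Y); d <- ncol(X)
  if (length(p_hat_r) != G) stopf("p_hat_r has wrong length")

  engine <- marginal_loglik_engine(Y, X, p_hat_r, n_quad, floor, scheme)
  obj <- function(u_free, coefs) {
    p_o <- softmax_reparam(c(u_free, 0))
    ll <- engine(p_o, coefs[1L], coefs[seq_len(d) + 1L],
                 coefs[d + 2L], coefs[seq_len(d) + d + 2L])
    sum(ll)
  }

  # init: u from floored mean stool proportions, gauge u_G = 0; coefs at 0
  p_bar <- floor_simplex(rowSums(Y) / sum(Y), 1e-8)
  u0 <- log(p_bar) - log(p_bar[G])
  u_free <- u0[-G]
  coefs <- numeric(2L * d + 2L)
  if (!is.null(init$u)) {
    u <- init$u - init$u[G]
    u_free <- u[-G]
  }
  if (!is.null(init$coefs)) coefs <- init$coefs

  L <- obj(u_free, coefs)
  if (!is.finite(L)) {
    stopf(paste0(
      "marginal log-likelihood is -Inf at initialization (a sample's ",
      "integrand underflows at every quadrature node); use fit_em() instead"))
  }
  ctrl <- list(fnscale = -1, maxit = inner_maxit, reltol = inner_reltol)
  trace <- numeric(0)
  converged <- FALSE
  m <- 0L
  while (m < max_outer) {
    m <- m + 1L
    # block 1: composition (softmax coordinates, last pinned at 0)
    o1 <- optim(u_free, function(u) obj(u, coefs), method = "Nelder-Mead",
                control = ctrl)
    if (is.finite(o1$value) && o1$value >= L) {
      u_free <- o1$par; L <- o1$value
    }
    # block 2: link coefficients
    o2 <- optim(coefs, function(cf) obj(u_free, cf), method = "Nelder-Mead",
                control = ctrl)
    if (is.finite(o2$value) && o2$value >= L) {
      coefs <- o2$par; L <- o2$value
    }
    trace <- c(trace, L)
    if (m > 1L && abs(trace[m] - trace[m - 1L]) <= tol) {
      converged <- TRUE
      break
    }
  }

  p_o_hat <- softmax_reparam(c(u_free, 0))
  names(p_o_hat) <- rownames(Y)
  p_hat_r <- setNames(p_hat_r, rownames(Y))
  theta_hat <- mixture_theta(
    p_r = p_hat_r, p_o = p_o_hat,
    beta0 = coefs[1L], beta = coefs[seq_len(d) + 1L],
    gamma0 = coefs[d + 2L], gamma = coefs[seq_len(d) + d + 2L]
  )
  structure(
    list(theta_hat = theta_hat, loglik = L, loglik_trace = trace,
         converged = converged, n_outer = m, method = "demix1",
         config = list(n_quad = n_quad, max_outer = max_outer, tol = tol,
                       inner_maxit = inner_maxit,
                       inner_reltol = inner_reltol, floor = floor,
                       scheme = scheme),
         taxa = rownames(Y)),
    class = "demix_fit"
  )
}

#' @export
print.demix_fit <- function(x, ...) {
  cat(sprintf("<demix_fit method = %s> %d taxa, %s after %d iteration(s)\n",
              x$method, length(x$theta_hat$p_o),
              if (x$converged) "converged" else "not converged", x$n_outer))
  cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  print(x$theta_hat)
  invisible(x)
}
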