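# Shared fixture builders; everything is generated in code at test time.

# Random point on the G-simplex (strictly positive).
random_simplex <- function(G) {
  w <- -log(runif(G))
  w / sum(w)
}

# Small random stool-like instance with its generating parameters.
random_small_instance <- function(G = 3, S = 2, N = 40, d = 1) {
  p_r <- random_simplex(G)
  p_o <- random_simplex(G)
  theta <- mixture_theta(
    p_r = p_r, p_o = p_o,
    beta0 = rnorm(1, 0, 0.3), beta = rnorm(d, 0, 0.3),
    gamma0 = rnorm(1, 0.3, 0.3), gamma = rnorm(d, 0, 0.3)
  )
  X <- matrix(rnorm(S * d), S, d)
  link <- link_mu_phi(X, theta)
  pi_i <- rbeta(S, link$a1, link$a2)
  Y <- vapply(seq_len(S), function(i) {
    rmultinom(1, N, pi_i[i] * p_r + (1 - pi_i[i]) * p_o)[, 1]
  }, numeric(G))
  Y <- matrix(Y, nrow = G,
              dimnames = list(paste0("t", seq_len(G)), paste0("s", seq_len(S))))
  list(Y = Y, X = X, theta = theta, pi = pi_i, link = link)
}

# Independent integration oracles for the marginal likelihood, written
# directly from the density factorization, not via the package's engine.

# Per-sample log integrand over the mixing proportion.
log_integrand_factory <- function(theta, y, a1, a2) {
  const <- lgamma(sum(y) + 1) - sum(lgamma(y + 1))
  function(t) {
    P <- outer(t, theta$p_r) + outer(1 - t, theta$p_o)
    const + drop(log(P) %*% y) + dbeta(t, a1, a2, log = TRUE)
  }
}

# Adaptive-quadrature (QUADPACK) oracle; robust to the integrable endpoint
# singularities that appear when a beta shape parameter is below 1.
adaptive_marginal_loglik <- function(theta, Y, X) {
  link <- link_mu_phi(X, theta)
  total <- 0
  for (i in seq_len(ncol(Y))) {
    lf <- log_integrand_factory(theta, Y[, i], link$a1[i], link$a2[i])
    shift <- max(lf(seq(0.001, 0.999, length.out = 2001)))
    val <- stats::integrate(function(t) exp(lf(t) - shift), 0, 1,
                            rel.tol = 1e-10, subdivisions = 400L)$value
    total <- total + shift + log(val)
  }
  total
}

# Midpoint-rule oracle on a fine grid; accurate for non-singular shapes
# (a1, a2 >= 1) and used where the spec calls for a plain dense grid.
trapezoid_marginal_loglik <- function(theta, Y, X, n_grid = 1e5) {
  grid <- seq(1 / (2 * n_grid), 1 - 1 / (2 * n_grid), length.out = n_grid)
  link <- link_mu_phi(X, theta)
  total <- 0
  for (i in seq_len(ncol(Y))) {
    lf <- log_integrand_factory(theta, Y[, i], link$a1[i], link$a2[i])(grid)
    m <- max(lf)
    total <- total + m + log(mean(exp(lf - m)))
  }
  total
}

# Multinomial log-likelihood at fixed proportions (independent of the
# package's internals; used for the null-reduction checks).
plain_multinomial_loglik <- function(Y, p) {
  sum(vapply(seq_len(ncol(Y)), function(i) {
    stats::dmultinom(Y[, i], prob = p, log = TRUE)
  }, numeric(1)))
}
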