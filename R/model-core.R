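#' Construct the full mixture parameter vector
#'
#' The model describes each stool sample as a two-component mixture: a
#' fraction \eqn{\pi_i} of its reads originates from the reference location
#' (rectum, composition `p_r`) and the remainder from other GI locations
#' (composition `p_o`). The latent \eqn{\pi_i} follows a beta distribution
#' whose mean and precision are linked to per-sample covariates:
#' \deqn{\mathrm{logit}(\mu_i) = \beta_0 + x_i^\top\beta, \qquad
#'       \log(\phi_i) = \gamma_0 + x_i^\top\gamma.}
#'
#' @param p_r,p_o Composition (simplex) vectors of equal length `G` for the
#'   reference location and the other locations.
#' @param beta0,gamma0 Intercepts of the mean (logit) and precision (log)
#'   links.
#' @param beta,gamma Covariate coefficient vectors of common length `d`
#'   (`d = 0` for an intercept-only model).
#'
#' @return An object of class `mixture_theta`.
#' @export
#'
#' @examples
#' mixture_theta(p_r = c(.5, .5), p_o = c(.2, .8))
mixture_theta <- function(p_r, p_o, beta0 = 0, beta = numeric(0),
                          gamma0 = 0, gamma = numeric(0)) {
  p_r <- as.numeric(p_r); p_o <- as.numeric(p_o)
  if (length(p_r) != length(p_o)) stopf("p_r and p_o must have equal length")
  assert_probability_vector(p_r, "p_r")
  assert_probability_vector(p_o, "p_o")
  beta <- as.numeric(beta); gamma <- as.numeric(gamma)
  if (length(beta) != length(gamma)) {
    stopf("beta and gamma must have the same length (covariate dimension)")
  }
  if (!all(is.finite(c(beta0, beta, gamma0, gamma)))) {
    stopf("link coefficients must be finite")
  }
  structure(
    list(p_r = p_r, p_o = p_o, beta0 = as.numeric(beta0), beta = beta,
         gamma0 = as.numeric(gamma0), gamma = gamma),
    class = "mixture_theta"
  )
}

#' @export
print.mixture_theta <- function(x, ...) {
  cat(sprintf("<mixture_theta> G = %d taxa, d = %d covariate(s)\n",
              length(x$p_r), length(x$beta)))
  cat("  p_r:", paste(signif(x$p_r, 3), collapse = " "), "\n")
  cat("  p_o:", paste(signif(x$p_o, 3), collapse = " "), "\n")
  cat(sprintf("  mean link:      beta0 = %.4g, beta = (%s)\n", x$beta0,
              paste(signif(x$beta, 4), collapse = ", ")))
  cat(sprintf("  precision link: gamma0 = %.4g, gamma = (%s)\n", x$gamma0,
              paste(signif(x$gamma, 4), collapse = ", ")))
  invisible(x)
}

#' Beta-regression link: covariates to beta shape parameters
#'
#' Maps each sample's covariate row to the mean/precision parameterization of
#' its mixing-proportion distribution and to the implied beta shapes
#' \eqn{a_{1,i} = \mu_i\phi_i}, \eqn{a_{2,i} = (1-\mu_i)\phi_i}.
#'
#' @param x A samples-by-covariates matrix (or a single covariate row, or
#'   `NULL` for intercept-only).
#' @param theta A [mixture_theta()] whose coefficient lengths match `ncol(x)`.
#'
#' @return A tibble with one row per sample and columns `mu`, `phi`, `a1`,
#'   `a2`.
#' @export
#'
#' @examples
#' th <- mixture_theta(c(.5, .5), c(.2, .8), beta0 = 0.1, beta = 0.1,
#'                     gamma0 = 0.2, gamma = 0.1)
#' link_mu_phi(matrix(c(-1, 0, 1)), th)
link_mu_phi <- function(x, theta) {
  d <- length(theta$beta)
  if (is.null(x)) {
    x <- matrix(numeric(0), nrow = 1L, ncol = 0L)
  } else if (!is.matrix(x) && !is.data.frame(x)) {
    # a bare vector is one covariate column when d == 1, else one sample row
    x <- if (d == 1L) matrix(as.numeric(x), ncol = 1L)
         else matrix(as.numeric(x), nrow = 1L)
  }
  x <- as_covariate_matrix(x, nrow(x))
  if (ncol(x) != d) {
    stopf("covariate dimension %d does not match coefficient length %d",
          ncol(x), d)
  }
  eta_mu  <- theta$beta0  + if (d) drop(x %*% theta$beta)  else 0
  eta_phi <- theta$gamma0 + if (d) drop(x %*% theta$gamma) else 0
  mu  <- stats::plogis(rep_len(eta_mu, nrow(x)))
  phi <- exp(rep_len(eta_phi, nrow(x)))
  tibble::tibble(mu = mu, phi = phi, a1 = mu * phi, a2 = (1 - mu) * phi)
}

#' Mixture of two compositions
#'
#' The per-sample stool composition \eqn{p_{ig} = \pi_i p^{(r)}_g +
#' (1-\pi_i) p^{(o)}_g}.
#'
#' @param pi_i Mixing proportion in `[0, 1]`.
#' @param p_r,p_o Simplex vectors of equal length.
#' @return A simplex vector.
#' @export
mix_proportions <- function(pi_i, p_r, p_o) {
  if (!is.finite(pi_i) || pi_i < 0 || pi_i > 1) {
    stopf("pi_i must lie in [0, 1], got %s", format(pi_i))
  }
  assert_probability_vector(p_r, "p_r")
  assert_probability_vector(p_o, "p_o")
  pi_i * p_r + (1 - pi_i) * p_o
}

# Multinomial log-pmf with log-gamma coefficient; p may contain zeros
# (y > 0 at a zero cell yields -Inf, by convention, not an error).
multinomial_logpmf <- function(y, p) {
  n <- sum(y)
  const <- lgamma(n + 1) - sum(lgamma(y + 1))
  logp <- ifelse(y > 0, y * log(p), 0)
  if (any(y > 0 & p == 0)) return(-Inf)
  const + sum(logp)
}

#' Joint log-density of one stool sample's counts and its mixing proportion
#'
#' Computes, entirely in log space,
#' \eqn{\log f(y_i, \pi_i) = \log \mathrm{Mult}(y_i; N_i, \pi_i p^{(r)} +
#' (1-\pi_i) p^{(o)}) + \log \mathrm{Beta}(\pi_i; a_1, a_2)}.
#' When a mixed proportion is exactly zero at a positive count the function
#' returns `-Inf` rather than raising an error; use the `floor` argument (or
#' the EM estimator) for that regime.
#'
#' @param y Non-negative integer count vector of length `G`.
#' @param pi_i Mixing proportion in `(0, 1)`.
#' @param theta A [mixture_theta()] (its `p_r`, `p_o` are used).
#' @param a1,a2 Beta shape parameters for this sample (e.g. one row of
#'   [link_mu_phi()]).
#' @param floor Optional floor applied to the mixture proportions inside the
#'   log (default 0 = no flooring).
#' @return A scalar log-density, possibly `-Inf`.
#' @export
joint_log_density <- function(y, pi_i, theta, a1, a2, floor = 0) {
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8)) {
    stopf("y must contain non-negative integers")
  }
  if (pi_i <= 0 || pi_i >= 1) stopf("pi_i must lie strictly in (0, 1)")
  p <- pi_i * theta$p_r + (1 - pi_i) * theta$p_o
  if (floor > 0) p <- floor_simplex(p, floor)
  multinomial_logpmf(y, p) + stats::dbeta(pi_i, a1, a2, log = TRUE)
}

#' Marginal mean and variance of a taxon's stool count
#'
#' Closed-form first two moments of \eqn{y_{ig}} under the mixture model,
#' obtained by conditioning on \eqn{\pi_i \sim \mathrm{Beta}(a_1, a_2)}:
#' the mean is \eqn{N_i\{p^{(r)}_g E\pi + p^{(o)}_g(1 - E\pi)\}} and the
#' variance combines the multinomial sampling variance with the extra
#' between-sample term \eqn{N_i^2 (p^{(r)}_g - p^{(o)}_g)^2
#' \mathrm{Var}(\pi_i)}. When \eqn{p^{(r)}_g = p^{(o)}_g} the variance
#' collapses to the plain multinomial \eqn{N_i p_g (1 - p_g)}.
#'
#' @param N_i Library size (positive integer).
#' @param a1,a2 Beta shape parameters (positive).
#' @param p_r_g,p_o_g The taxon's proportion in the two locations.
#' @return A tibble with columns `mean` and `variance`.
#' @export
moments_y <- function(N_i, a1, a2, p_r_g, p_o_g) {
  if (any(a1 <= 0) || any(a2 <= 0)) stopf("beta shapes must be positive")
  if (any(N_i <= 0)) stopf("N_i must be positive")
  m1 <- a1 / (a1 + a2)                               # E(pi)
  m2 <- m1 * (a1 + 1) / (a1 + a2 + 1)                # E(pi^2)
  vpi <- m2 - m1^2
  dp <- p_r_g - p_o_g
  ep  <- p_o_g + m1 * dp                             # E(p_g(pi))
  ep2 <- p_o_g^2 + 2 * p_o_g * dp * m1 + dp^2 * m2   # E(p_g(pi)^2)
  tibble::tibble(
    mean = N_i * ep,
    variance = N_i * (ep - ep2) + N_i^2 * dp^2 * vpi
  )
}
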