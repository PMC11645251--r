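# Global test of H0: p(o) = p(r) based on the multinomial central limit
# theorem. Under the null the mixture model reduces to a plain multinomial,
# both composition estimators are asymptotically normal with covariance
# V(p)/N_total, and the squared-distance statistic's null distribution can
# be simulated directly.

#' Multinomial covariance matrix of a composition
#'
#' \eqn{V(p)} with diagonal \eqn{p_g(1-p_g)} and off-diagonal
#' \eqn{-p_g p_h}; symmetric, positive semidefinite, with \eqn{V 1 = 0}.
#'
#' @param p Simplex vector.
#' @return A `G x G` matrix.
#' @export
multinomial_cov <- function(p) {
  assert_probability_vector(p, "p")
  diag(p) - tcrossprod(p)
}

#' Squared-distance test statistic between two compositions
#'
#' \eqn{\hat T = \|\hat p^{(o)} - \hat p^{(r)}\|_2^2}.
#'
#' @param p_hat_r,p_hat_o Simplex vectors of equal length.
#' @return A non-negative scalar.
#' @export
test_stat <- function(p_hat_r, p_hat_o) {
  if (length(p_hat_r) != length(p_hat_o)) stopf("length mismatch")
  sum((p_hat_o - p_hat_r)^2)
}

#' Simulate the asymptotic null distribution of the test statistic
#'
#' Under the null both estimated compositions deviate from the common truth
#' by asymptotically normal errors: \eqn{\sqrt{N}(\hat p - p) \to
#' N_G(0, V(p))}. Each draw simulates the two deviations
#' \eqn{d_r = v_1/\sqrt{N^{(r)}}} and \eqn{d_o = v_2/\sqrt{N}} with
#' independent \eqn{v_1, v_2 \sim N_G(0, V(\hat p^{(r)}))} and returns
#' \eqn{\|d_o - d_r\|_2^2}. `scaling = "over_n"` divides by the totals
#' instead of their square roots; that variant shrinks the null scale as
#' \eqn{1/N^2}, is inconsistent with the multinomial variance of the
#' estimated proportions, and is provided only for comparison.
#'
#' @param p_hat_r Reference composition estimate under which the null is
#'   simulated.
#' @param N_r_total,N_total Summed library sizes of the reference and stool
#'   groups.
#' @param B Number of draws.
#' @param seed Integer seed, or `NULL`.
#' @param scaling `"sqrt"` (default) or `"over_n"`.
#' @return A numeric vector of `B` null draws of \eqn{\hat T}.
#' @export
sample_null_T <- function(p_hat_r, N_r_total, N_total, B = 10000,
                          seed = NULL, scaling = c("sqrt", "over_n")) {
  scaling <- match.arg(scaling)
  assert_probability_vector(p_hat_r, "p_hat_r")
  if (N_r_total <= 0 || N_total <= 0) stopf("totals must be positive")
  V <- multinomial_cov(p_hat_r)
  with_seed_(seed, {
    v1 <- MASS::mvrnorm(B, mu = rep(0, length(p_hat_r)), Sigma = V,
                        tol = 1e-10)
    v2 <- MASS::mvrnorm(B, mu = rep(0, length(p_hat_r)), Sigma = V,
                        tol = 1e-10)
    den_r <- if (scaling == "sqrt") sqrt(N_r_total) else N_r_total
    den_o <- if (scaling == "sqrt") sqrt(N_total) else N_total
    diff <- v2 / den_o - v1 / den_r
    rowSums(diff^2)
  })
}

# Shared p-value formula: add-one Monte-Carlo estimate, never exactly 0.
mc_pvalue <- function(T_obs, null_draws) {
  (1 + sum(null_draws >= T_obs)) / (1 + length(null_draws))
}

new_demix_test <- function(T_obs, p_value, B, method, null_draws, extra = list()) {
  structure(
    c(list(statistic = T_obs, p_value = p_value, B = B, method = method,
           null_draws = null_draws), extra),
    class = "demix_test"
  )
}

#' @export
print.demix_test <- function(x, ...) {
  cat(sprintf("<demix_test method = %s> T = %.6g, p = %.4g (B = %d)\n",
              x$method, x$statistic, x$p_value, x$B))
  invisible(x)
}

#' Monte-Carlo p-value from simulated null draws
#'
#' \eqn{\hat p = (1 + \#\{\hat T_b \ge \hat T\}) / (1 + B)}; the observed
#' statistic participates through the add-one terms, so the p-value is never
#' below \eqn{1/(1+B)}.
#'
#' @param T_obs Observed statistic.
#' @param null_draws Vector of simulated null statistics.
#' @return A `demix_test` object with `method = "asymptotic"`.
#' @export
asymptotic_pvalue <- function(T_obs, null_draws) {
  new_demix_test(T_obs, mc_pvalue(T_obs, null_draws), length(null_draws),
                 "asymptotic", null_draws)
}

#' Asymptotic global test of compositional equality
#'
#' Tests H0: the other-location composition equals the reference
#' composition. Estimates the reference composition by pooling
#' ([estimate_p_r()]), the other-location composition by the direct marginal
#' MLE ([fit_demix1()]), forms \eqn{\hat T = \|\hat p^{(o)} -
#' \hat p^{(r)}\|^2}, and compares it with `B` draws from the simulated
#' asymptotic null ([sample_null_T()]).
#'
#' @param stool,rectum Taxa-by-samples count matrices (shared taxa, same
#'   order).
#' @param X Stool covariates (samples x d matrix or `NULL`).
#' @param B Number of null draws (default 10000).
#' @param seed Integer seed for the null simulation, or `NULL`.
#' @param fit Optional precomputed `demix_fit` for the stool data (skips the
#'   refit).
#' @param scaling Passed to [sample_null_T()].
#' @param ... Further arguments to [fit_demix1()].
#' @return A `demix_test` object; `fit` carries the underlying model fit.
#' @export
test_asymptotic <- function(stool, rectum, X = NULL, B = 10000, seed = NULL,
                            fit = NULL, scaling = "sqrt", ...) {
  stool <- as_count_matrix(stool)
  rectum <- as_count_matrix(rectum)
  if (!identical(rownames(stool), rownames(rectum))) {
    stopf("stool and rectum must share the same taxa in the same order")
  }
  p_hat_r <- estimate_p_r(rectum)
  if (is.null(fit)) {
    fit <- fit_demix1(stool, X, p_hat_r, ...)
  }
  T_obs <- test_stat(p_hat_r, fit$theta_hat$p_o)
  draws <- sample_null_T(p_hat_r, sum(rectum), sum(stool), B = B,
                         seed = seed, scaling = scaling)
  out <- asymptotic_pvalue(T_obs, draws)
  out$fit <- fit
  out
}
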