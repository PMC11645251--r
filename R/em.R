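# Monte-Carlo EM estimator. The E-step replaces the intractable conditional
# expectation of the joint log-likelihood by an average over
# Metropolis-Hastings draws of the latent mixing proportions; the M-step
# maximizes that average with Nelder-Mead. Because the joint log-likelihood
# takes logs of the mixture proportions term-by-term it never underflows,
# which is what makes this estimator usable for very rare taxa or very deep
# libraries where the marginal likelihood evaluates to -Inf.

#' Joint log-likelihood of counts and latent mixing proportions
#'
#' \eqn{\ell_{joint}(\theta; Y, \pi) = \sum_i \log f(y_i, \pi_i \mid \theta)},
#' the complete-data log-likelihood summed over samples.
#'
#' @param theta A [mixture_theta()].
#' @param stool Taxa-by-samples count matrix.
#' @param X Samples-by-covariates matrix or `NULL`.
#' @param pi Vector of mixing proportions, strictly inside `(0, 1)`, one per
#'   sample.
#' @param floor Proportion floor inside logs (default 1e-12).
#' @return Scalar log-likelihood (finite whenever floored proportions are
#'   positive).
#' @export
joint_loglik <- function(theta, stool, X = NULL, pi, floor = 1e-12) {
  Y <- as_count_matrix(stool)
  X <- as_covariate_matrix(X, ncol(Y))
  if (length(pi) != ncol(Y)) stopf("pi must have one entry per sample")
  if (any(pi <= 0) || any(pi >= 1)) stopf("pi must lie strictly in (0, 1)")
  sh <- beta_shapes(X, theta$beta0, theta$beta, theta$gamma0, theta$gamma)
  tY <- t(Y)
  const <- lgamma(colSums(Y) + 1) - colSums(lgamma(Y + 1))
  P <- outer(pi, theta$p_r) + outer(1 - pi, theta$p_o)
  if (floor > 0 && any(P < floor)) {
    P <- pmax(P, floor)
    P <- P / rowSums(P)
  }
  sum(const + rowSums(tY * log(P)) +
        dbeta(pi, sh$a1, sh$a2, log = TRUE))
}

#' Metropolis-Hastings sampler for the latent mixing proportions
#'
#' Runs one independent random-walk chain per sample targeting
#' \eqn{f(\pi_i \mid y_i, \theta) \propto f(y_i, \pi_i \mid \theta)}, with a
#' Gaussian proposal on \eqn{\mathrm{logit}(\pi_i)}. During burn-in each
#' chain's step size adapts multiplicatively toward an acceptance rate of
#' about 0.35 and is then frozen, so the retained draws target the exact
#' conditional. All chains are advanced jointly (vectorized over samples).
#'
#' @param stool Taxa-by-samples count matrix.
#' @param X Samples-by-covariates matrix or `NULL`.
#' @param theta A [mixture_theta()].
#' @param M Number of retained draws per sample (default 50).
#' @param step Initial random-walk step on the logit scale (default 0.5).
#' @param burnin Burn-in iterations (default 200).
#' @param thin Thinning interval (default 5).
#' @param seed Integer seed or `NULL`.
#' @param floor Proportion floor inside logs (default 1e-12).
#' @return A list of class `pi_draws`: `draws` (`M x S` matrix in `(0,1)`),
#'   `acceptance_rate` (per sample, post-burn-in), `step` (final per-chain
#'   steps).
#' @export
mh_sample_pi <- function(stool, X = NULL, theta, M = 50, step = 0.5,
                         burnin = 200, thin = 5, seed = NULL, floor = 1e-12) {
  Y <- as_count_matrix(stool)
  X <- as_covariate_matrix(X, ncol(Y))
  S <- ncol(Y)
  sh <- beta_shapes(X, theta$beta0, theta$beta, theta$gamma0, theta$gamma)
  tY <- t(Y)
  p_r <- theta$p_r; p_o <- theta$p_o

  # unnormalized log target on the logit scale (includes the Jacobian)
  logit_target <- function(z) {
    pi <- stats::plogis(z)
    P <- outer(pi, p_r) + outer(1 - pi, p_o)
    if (floor > 0 && any(P < floor)) {
      P <- pmax(P, floor)
      P <- P / rowSums(P)
    }
    rowSums(tY * log(P)) + sh$a1 * log(pi) + sh$a2 * log1p(-pi)
    # (a1-1)log(pi) + (a2-1)log(1-pi) + Jacobian log(pi(1-pi)) collapses
    # to a1*log(pi) + a2*log(1-pi)
  }

  with_seed_(seed, {
    z <- stats::qlogis(pmin(pmax(sh$a1 / (sh$a1 + sh$a2), 0.02), 0.98))
    h <- logit_target(z)
    step_i <- rep_len(step, S)
    accepted <- numeric(S)
    block_acc <- numeric(S)
    draws <- matrix(NA_real_, M, S)
    n_keep <- 0L
    total_post <- 0L
    iter <- 0L
    adapt_block <- 25L
    while (n_keep < M) {
      iter <- iter + 1L
      z_prop <- z + step_i * rnorm(S)
      h_prop <- logit_target(z_prop)
      acc <- log(runif(S)) < (h_prop - h)
      z[acc] <- z_prop[acc]
      h[acc] <- h_prop[acc]
      if (iter <= burnin) {
        block_acc <- block_acc + acc
        if (iter %% adapt_block == 0L) {
          rate <- block_acc / adapt_block
          step_i <- step_i * exp(rate - 0.35)
          block_acc[] <- 0
        }
      } else {
        accepted <- accepted + acc
        total_post <- total_post + 1L
        if ((iter - burnin) %% thin == 0L) {
          n_keep <- n_keep + 1L
          draws[n_keep, ] <- stats::plogis(z)
        }
      }
    }
    rate <- accepted / total_post
    if (all(rate == 0)) {
      stopf("Metropolis-Hastings accepted no proposals; try a smaller step")
    }
    structure(list(draws = draws, acceptance_rate = rate, step = step_i),
              class = "pi_draws")
  })
}

# Reusable engine for the Monte-Carlo E-step objective; returns
# function(p_o, coefs, PI, idx) where PI stacks the draws column-major
# (draw m of sample i at position (i-1)*M + m is irrelevant; idx maps each
# entry of PI to its sample).
approx_Q_engine <- function(Y, X, p_r, floor) {
  tY <- t(Y)
  const <- lgamma(colSums(Y) + 1) - colSums(lgamma(Y + 1))
  d <- ncol(X)
  function(p_o, beta0, beta, gamma0, gamma, PI, idx, M) {
    P <- outer(PI, p_r) + outer(1 - PI, p_o)
    if (floor > 0 && any(P < floor)) {
      P <- pmax(P, floor)
      P <- P / rowSums(P)
    }
    mult <- rowSums(tY[idx, , drop = FALSE] * log(P))
    sh <- beta_shapes(X, beta0, beta, gamma0, gamma)
    bl <- dbeta(PI, sh$a1[idx], sh$a2[idx], log = TRUE)
    sum(mult + bl) / M + sum(const)
  }
}

#' Monte-Carlo approximation of the EM objective
#'
#' \eqn{\tilde Q(\theta) = M^{-1}\sum_m \ell_{joint}(\theta; Y,
#' \tilde\pi_m)}, the average of the joint log-likelihood over the current
#' posterior draws of the latent mixing proportions.
#'
#' @param theta A [mixture_theta()].
#' @param stool Taxa-by-samples count matrix.
#' @param X Samples-by-covariates matrix or `NULL`.
#' @param pi_draws A `pi_draws` object from [mh_sample_pi()].
#' @param floor Proportion floor (default 1e-12).
#' @return Scalar objective value.
#' @export
approx_Q <- function(theta, stool, X = NULL, pi_draws, floor = 1e-12) {
  Y <- as_count_matrix(stool)
  X <- as_covariate_matrix(X, ncol(Y))
  draws <- pi_draws$draws
  M <- nrow(draws); S <- ncol(draws)
  if (S != ncol(Y)) stopf("pi_draws do not match the number of samples")
  engine <- approx_Q_engine(Y, X, theta$p_r, floor)
  idx <- rep(seq_len(S), each = M)
  engine(theta$p_o, theta$beta0, theta$beta, theta$gamma0, theta$gamma,
         as.vector(draws), idx, M)
}

#' Fit the mixture model by Monte-Carlo EM
#'
#' Alternates an E-step (Metropolis-Hastings draws of the latent mixing
#' proportions given the current parameters) with an M-step (Nelder-Mead
#' maximization of the Monte-Carlo EM objective over the softmax coordinates
#' of the other-location composition and the link coefficients jointly; a
#' blocked variant mirroring the direct fitter's two blocks is available).
#' The reference composition stays fixed at its plug-in value. Iteration
#' stops when the L1 change in the parameter vector is at most `tol` on two
#' consecutive iterations (the doubled check guards against a single lucky
#' Monte-Carlo fluctuation), or after `K` iterations.
#'
#' @param stool Taxa-by-samples count matrix.
#' @param X Samples-by-covariates matrix or `NULL`.
#' @param p_hat_r Reference composition (e.g. [estimate_p_r()]).
#' @param K Maximum EM iterations (default 30).
#' @param M Monte-Carlo draws per E-step (default 50).
#' @param tol L1 convergence threshold on the parameter change (default
#'   0.0001).
#' @param step,burnin,thin Metropolis-Hastings controls (see
#'   [mh_sample_pi()]).
#' @param inner_maxit,inner_reltol Nelder-Mead budget for the M-step.
#' @param blocked Use two Nelder-Mead blocks (composition, then
#'   coefficients) instead of one joint search (default `FALSE`).
#' @param floor Proportion floor (default 1e-12).
#' @param seed Integer seed or `NULL`; the whole fit is reproducible from it.
#' @param init Optional list with `u` and/or `coefs` overriding the default
#'   initialization (shared with [fit_demix1()]).
#' @return A `demix_fit` object with `method = "em"`; `loglik_trace` holds
#'   the per-iteration observed-data (marginal) log-likelihood, computed for
#'   diagnostics only and possibly `-Inf` when it underflows.
#' @export
fit_em <- function(stool, X = NULL, p_hat_r, K = 30, M = 50, tol = 1e-4,
                   step = 0.5, burnin = 200, thin = 5, inner_maxit = 1500,
                   inner_reltol = 1e-6, blocked = FALSE, floor = 1e-12,
                   seed = NULL, init = NULL) {
  Y <- as_count_matrix(stool)
  X <- as_covariate_matrix(X, ncol(Y))
  assert_probability_vector(p_hat_r, "p_hat_r")
  G <- nrow(Y); d <- ncol(X); S <- ncol(Y)
  if (length(p_hat_r) != G) stopf("p_hat_r has wrong length")

  engine <- approx_Q_engine(Y, X, p_hat_r, floor)
  idx <- rep(seq_len(S), each = M)

  p_bar <- floor_simplex(rowSums(Y) / sum(Y), 1e-8)
  u0 <- log(p_bar) - log(p_bar[G])
  u_free <- u0[-G]
  coefs <- numeric(2L * d + 2L)
  if (!is.null(init$u)) {
    u <- init$u - init$u[G]
    u_free <- u[-G]
  }
  if (!is.null(init$coefs)) coefs <- init$coefs

  theta_from <- function(u_free, coefs) {
    mixture_theta(
      p_r = p_hat_r, p_o = softmax_reparam(c(u_free, 0)),
      beta0 = coefs[1L], beta = coefs[seq_len(d) + 1L],
      gamma0 = coefs[d + 2L], gamma = coefs[seq_len(d) + d + 2L]
    )
  }
  ctrl <- list(fnscale = -1, maxit = inner_maxit, reltol = inner_reltol)

  with_seed_(seed, {
    trace <- numeric(0)
    converged <- FALSE
    hit <- 0L
    k <- 0L
    acc_rate <- NULL
    while (k < K) {
      k <- k + 1L
      theta_prev <- theta_from(u_free, coefs)
      # E-step: fresh draws under the current parameters
      pdraws <- mh_sample_pi(Y, X, theta_prev, M = M, step = step,
                             burnin = burnin, thin = thin, floor = floor)
      acc_rate <- pdraws$acceptance_rate
      PI <- as.vector(pdraws$draws)
      qfun <- function(u_free, coefs) {
        engine(softmax_reparam(c(u_free, 0)), coefs[1L],
               coefs[seq_len(d) + 1L], coefs[d + 2L],
               coefs[seq_len(d) + d + 2L], PI, idx, M)
      }
      # M-step
      if (blocked) {
        o1 <- optim(u_free, function(u) qfun(u, coefs),
                    method = "Nelder-Mead", control = ctrl)
        u_free <- o1$par
        o2 <- optim(coefs, function(cf) qfun(u_free, cf),
                    method = "Nelder-Mead", control = ctrl)
        coefs <- o2$par
      } else {
        o <- optim(c(u_free, coefs), function(par) {
          qfun(par[seq_len(G - 1L)], par[-seq_len(G - 1L)])
        }, method = "Nelder-Mead", control = ctrl)
        u_free <- o$par[seq_len(G - 1L)]
        coefs <- o$par[-seq_len(G - 1L)]
      }
      theta_new <- theta_from(u_free, coefs)
      trace <- c(trace, marginal_loglik(theta_new, Y, X, floor = floor))
      dtheta <- sum(abs(theta_new$p_o - theta_prev$p_o)) +
        abs(theta_new$beta0 - theta_prev$beta0) +
        sum(abs(theta_new$beta - theta_prev$beta)) +
        abs(theta_new$gamma0 - theta_prev$gamma0) +
        sum(abs(theta_new$gamma - theta_prev$gamma))
      hit <- if (dtheta <= tol) hit + 1L else 0L
      if (hit >= 2L) {
        converged <- TRUE
        break
      }
    }
    theta_hat <- theta_from(u_free, coefs)
    names(theta_hat$p_o) <- rownames(Y)
    names(theta_hat$p_r) <- rownames(Y)
    structure(
      list(theta_hat = theta_hat, loglik = trace[length(trace)],
           loglik_trace = trace, converged = converged, n_outer = k,
           method = "em", acceptance_rate = acc_rate,
           config = list(K = K, M = M, tol = tol, step = step,
                         burnin = burnin, thin = thin,
                         inner_maxit = inner_maxit, blocked = blocked,
                         floor = floor),
           taxa = rownames(Y)),
      class = "demix_fit"
    )
  })
}
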