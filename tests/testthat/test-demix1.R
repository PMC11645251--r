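test_that("softmax reparameterization is stable and shift-invariant", {
  expect_equal(softmax_reparam(rep(0, 4)), rep(0.25, 4))
  set.seed(31)
  u <- rnorm(6)
  expect_equal(softmax_reparam(u), softmax_reparam(u + 3.7), tolerance = 1e-14)
  # extreme values do not overflow
  expect_equal(sum(softmax_reparam(c(1000, 999, 0))), 1)
})

test_that("marginal likelihood reduces to the multinomial under equal compositions", {
  set.seed(37)
  for (r in 1:10) {
    G <- sample(2:6, 1)
    p <- random_simplex(G)
    th <- mixture_theta(p, p, beta0 = rnorm(1), beta = rnorm(1),
                        gamma0 = rnorm(1), gamma = rnorm(1))
    S <- sample(1:4, 1)
    X <- matrix(rnorm(S), S, 1)
    Y <- rmultinom(S, 50, p)
    rownames(Y) <- paste0("t", seq_len(G))
    expect_equal(marginal_loglik(th, Y, X),
                 plain_multinomial_loglik(Y, p), tolerance = 1e-10)
  }
  # the two-count uniform case evaluates to log(1/2)
  thu <- mixture_theta(c(.5, .5), c(.5, .5))
  Y1 <- matrix(c(1, 1), 2, dimnames = list(c("a", "b"), "s"))
  expect_equal(marginal_loglik(thu, Y1), log(0.5), tolerance = 1e-12)
})

test_that("quadrature marginal matches adaptive integration", {
  set.seed(41)
  for (r in 1:10) {
    inst <- random_small_instance(G = sample(2:4, 1), S = sample(1:3, 1))
    got <- marginal_loglik(inst$theta, inst$Y, inst$X, n_quad = 60)
    want <- adaptive_marginal_loglik(inst$theta, inst$Y, inst$X)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("grid integration of the joint density recovers the marginal", {
  # non-singular shapes (phi > 2) so the plain fine grid is itself accurate
  set.seed(43)
  p_r <- random_simplex(3); p_o <- random_simplex(3)
  theta <- mixture_theta(p_r, p_o, beta0 = 0.2, gamma0 = 1.3)
  Y <- rmultinom(1, 60, 0.5 * p_r + 0.5 * p_o)
  rownames(Y) <- paste0("t", 1:3)
  bl <- link_mu_phi(NULL, theta)
  grid_n <- 5e4
  grid <- seq(1 / (2 * grid_n), 1 - 1 / (2 * grid_n), length.out = grid_n)
  lf <- vapply(grid, function(t) {
    joint_log_density(Y[, 1], t, theta, bl$a1, bl$a2)
  }, numeric(1))
  m <- max(lf)
  want <- m + log(mean(exp(lf - m)))
  got <- marginal_loglik(theta, Y, NULL, n_quad = 40)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("fitted composition saturates in the number of quadrature nodes", {
  des <- sim_design(G = 4, S = 30, S_r = 30, N = 500)
  sim <- simulate_dataset(des, seed = 47)
  phr <- estimate_p_r(sim$rectum)
  # a tight optimizer profile isolates quadrature sensitivity from
  # Nelder-Mead stopping noise (which is an order of magnitude larger at
  # the default tolerances)
  fits <- lapply(c(20, 40, 80), function(q) {
    fit_demix1(sim$stool, sim$covariates, phr, n_quad = q,
               inner_reltol = 1e-10, inner_maxit = 8000, tol = 1e-5,
               max_outer = 100)$theta_hat$p_o
  })
  expect_lt(max(abs(fits[[1]] - fits[[2]])), 1e-4)
  expect_lt(max(abs(fits[[2]] - fits[[3]])), 1e-4)
  # the objective itself is converged in the node count at fixed parameters
  th <- mixture_theta(phr, fits[[2]], beta0 = 0.1, beta = 0.1,
                      gamma0 = 0.2, gamma = 0.1)
  l40 <- marginal_loglik(th, sim$stool, sim$covariates, n_quad = 40)
  l160 <- marginal_loglik(th, sim$stool, sim$covariates, n_quad = 160)
  expect_lt(abs(l40 - l160), 1e-5)
})

test_that("under equal true compositions the fit recovers the reference", {
  for (s in c(53, 59)) {
    des <- sim_design(G = 5, S = 100, S_r = 100, N = 5000,
                      mode = "shifted_pr", delta = 0)
    sim <- simulate_dataset(des, seed = s)
    phr <- estimate_p_r(sim$rectum)
    fit <- fit_demix1(sim$stool, sim$covariates, phr)
    expect_lt(max(abs(fit$theta_hat$p_o - phr)), 0.02)
  }
})

test_that("block-coordinate objective trace is monotone non-decreasing", {
  des <- sim_design(G = 5, S = 40, S_r = 40, N = 1000)
  sim <- simulate_dataset(des, seed = 61)
  fit <- fit_demix1(sim$stool, sim$covariates, estimate_p_r(sim$rectum))
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  expect_true(fit$converged)
})

test_that("a structurally impossible composition raises the use-EM error", {
  # taxon absent from the reference, present in stool, and started at a
  # numerically zero other-location mass: every node integrand is -Inf
  Y <- matrix(c(5, 10, 4, 12), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  p_hat_r <- c(0, 1)
  th <- mixture_theta(p_hat_r, softmax_reparam(c(0, 800)))
  ll <- marginal_loglik(th, Y, NULL)
  expect_identical(as.numeric(ll), -Inf)
  expect_equal(sort(attr(ll, "bad_samples")), c("s1", "s2"))
  expect_error(
    fit_demix1(Y, NULL, p_hat_r, floor = 0, init = list(u = c(0, 800))),
    "fit_em"
  )
})
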