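test_that("joint log-likelihood is the sum of per-sample joint densities", {
  set.seed(83)
  inst <- random_small_instance(G = 4, S = 3)
  pi <- runif(3, 0.1, 0.9)
  got <- joint_loglik(inst$theta, inst$Y, inst$X, pi, floor = 0)
  want <- sum(vapply(1:3, function(i) {
    joint_log_density(inst$Y[, i], pi[i], inst$theta,
                      inst$link$a1[i], inst$link$a2[i])
  }, numeric(1)))
  expect_equal(got, want, tolerance = 1e-10)

  # jointly reordering samples leaves the sum unchanged
  ord <- c(3, 1, 2)
  expect_equal(joint_loglik(inst$theta, inst$Y[, ord], inst$X[ord, ,
               drop = FALSE], pi[ord], floor = 0), got, tolerance = 1e-10)
})

test_that("joint likelihood stays finite where the marginal is -Inf", {
  Y <- matrix(c(5, 10, 4, 12), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  th <- mixture_theta(c(0, 1), softmax_reparam(c(0, 800)))
  expect_identical(as.numeric(marginal_loglik(th, Y, NULL)), -Inf)
  expect_true(is.finite(joint_loglik(th, Y, NULL, pi = c(0.4, 0.6))))
})

test_that("MH sampler targets the exact conditional of the mixing proportion", {
  # under equal compositions the counts drop out; with unit shapes the
  # target is exactly uniform on (0, 1)
  p <- c(.4, .6)
  th <- mixture_theta(p, p)  # intercepts 0 give a1 = a2 = 0.5
  thu <- mixture_theta(p, p, gamma0 = log(2))  # phi = 2 -> a1 = a2 = 1
  Y <- matrix(c(12, 18, 9, 21), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  dr <- mh_sample_pi(Y, NULL, thu, M = 4000, burnin = 300, thin = 2,
                     seed = 89)
  expect_true(all(dr$draws > 0 & dr$draws < 1))
  # uniform target: mean 1/2 within 3 Monte-Carlo standard errors (draws
  # are autocorrelated; use an inflated effective-sample-size guard)
  expect_lt(abs(mean(dr$draws[, 1]) - 0.5), 3 * sqrt(1 / 12 / (4000 / 8)))
  expect_lt(suppressWarnings(
    ks.test(dr$draws[, 1], "punif")$statistic), 0.05)
  expect_true(all(dr$acceptance_rate > 0.05))
})

test_that("Monte-Carlo EM objective averages the joint log-likelihood", {
  set.seed(97)
  inst <- random_small_instance(G = 3, S = 4)
  dr <- mh_sample_pi(inst$Y, inst$X, inst$theta, M = 6, burnin = 30,
                     thin = 1, seed = 97)
  # M = 1 reduces to the joint log-likelihood at the single draw
  one <- list(draws = dr$draws[1, , drop = FALSE])
  expect_equal(approx_Q(inst$theta, inst$Y, inst$X, one),
               joint_loglik(inst$theta, inst$Y, inst$X, dr$draws[1, ]),
               tolerance = 1e-10)
  # averaging two half-batches equals the full average
  h1 <- list(draws = dr$draws[1:3, , drop = FALSE])
  h2 <- list(draws = dr$draws[4:6, , drop = FALSE])
  full <- approx_Q(inst$theta, inst$Y, inst$X, list(draws = dr$draws))
  expect_equal((approx_Q(inst$theta, inst$Y, inst$X, h1) +
                  approx_Q(inst$theta, inst$Y, inst$X, h2)) / 2,
               full, tolerance = 1e-10)
})

test_that("Monte-Carlo variance of the EM objective shrinks like 1/M", {
  des <- sim_design(G = 3, S = 6, S_r = 4, N = 200)
  sim <- simulate_dataset(des, seed = 101)
  th <- sim$truth
  v <- vapply(c(10, 160), function(M) {
    qs <- vapply(1:24, function(r) {
      dr <- mh_sample_pi(sim$stool, sim$covariates, th, M = M, burnin = 80,
                         thin = 3, seed = 1000 + 17 * M + r)
      approx_Q(th, sim$stool, sim$covariates, dr)
    }, numeric(1))
    stats::var(qs)
  }, numeric(1))
  # a 16-fold increase in draws should shrink the variance roughly 16-fold;
  # accept a broad band around it to absorb Monte-Carlo noise
  expect_gt(v[1] / v[2], 4)
})

test_that("EM is seed-reproducible and its diagnostics trace ascends", {
  des <- sim_design(G = 3, S = 8, S_r = 8, N = 300)
  sim <- simulate_dataset(des, seed = 103)
  phr <- estimate_p_r(sim$rectum)
  f1 <- fit_em(sim$stool, sim$covariates, phr, K = 3, M = 20, burnin = 60,
               seed = 104)
  f2 <- fit_em(sim$stool, sim$covariates, phr, K = 3, M = 20, burnin = 60,
               seed = 104)
  expect_identical(f1$theta_hat, f2$theta_hat)
  f3 <- fit_em(sim$stool, sim$covariates, phr, K = 3, M = 20, burnin = 60,
               seed = 105)
  expect_false(identical(f1$theta_hat$p_o, f3$theta_hat$p_o))

  # with many draws per E-step the observed-data log-likelihood trace is
  # non-decreasing up to Monte-Carlo slack
  f <- fit_em(sim$stool, sim$covariates, phr, K = 5, M = 500, burnin = 150,
              thin = 2, seed = 106)
  expect_true(all(diff(f$loglik_trace) > -1))
})

test_that("EM recovers the composition on a moderately large taxon set", {
  des <- sim_design(G = 20, S = 100, S_r = 100, N = 10000)
  sim <- simulate_dataset(des, seed = 107)
  fe <- fit_em(sim$stool, sim$covariates, estimate_p_r(sim$rectum),
               K = 8, M = 20, burnin = 100, inner_maxit = 2500, seed = 108)
  p_o <- des$truth$p_o
  expect_lt(sum((p_o - fe$theta_hat$p_o)^2) / sum(p_o^2), 0.05)
})
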