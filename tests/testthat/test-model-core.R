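test_that("beta-regression links map covariates to shapes correctly", {
  th0 <- mixture_theta(c(.5, .5), c(.2, .8))
  bl <- link_mu_phi(NULL, th0)
  expect_equal(bl$mu, 0.5)
  expect_equal(bl$phi, 1)
  expect_equal(bl$a1, 0.5)
  expect_equal(bl$a2, 0.5)

  th <- mixture_theta(c(.5, .5), c(.2, .8), beta0 = 0.1, gamma0 = 0.2)
  bl <- link_mu_phi(NULL, th)
  expect_equal(bl$mu, 1 / (1 + exp(-0.1)))
  expect_equal(bl$phi, exp(0.2))

  # shape parameterization round-trips mean and precision exactly
  set.seed(11)
  for (r in 1:25) {
    thr <- mixture_theta(c(.5, .5), c(.2, .8), beta0 = rnorm(1),
                         beta = rnorm(2), gamma0 = rnorm(1), gamma = rnorm(2))
    x <- matrix(rnorm(8), 4, 2)
    bl <- link_mu_phi(x, thr)
    expect_equal(bl$a1 / (bl$a1 + bl$a2), bl$mu, tolerance = 1e-12)
    expect_equal(bl$a1 + bl$a2, bl$phi, tolerance = 1e-12)
    expect_true(all(bl$a1 > 0 & bl$a2 > 0))
  }

  expect_error(link_mu_phi(matrix(Inf), th0), "finite")
})

test_that("mixed composition is the convex combination and stays a simplex", {
  p_r <- c(.5, .5); p_o <- c(.2, .8)
  expect_identical(mix_proportions(1, p_r, p_o), p_r)
  expect_identical(mix_proportions(0, p_r, p_o), p_o)
  expect_equal(mix_proportions(0.5, p_r, p_o), c(0.35, 0.65))
  expect_error(mix_proportions(1.2, p_r, p_o), "0, 1")

  set.seed(7)
  for (r in 1:50) {
    G <- sample(2:8, 1)
    p <- mix_proportions(runif(1), random_simplex(G), random_simplex(G))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
})

test_that("joint log-density is multinomial log-pmf plus beta log-pdf", {
  th <- mixture_theta(c(.5, .5), c(.5, .5))
  expect_equal(joint_log_density(c(1, 1), 0.3, th, a1 = 1, a2 = 1),
               log(0.5))

  set.seed(13)
  for (r in 1:25) {
    inst <- random_small_instance(G = sample(2:5, 1), S = 1)
    pi_i <- runif(1, 0.05, 0.95)
    got <- joint_log_density(inst$Y[, 1], pi_i, inst$theta,
                             inst$link$a1[1], inst$link$a2[1])
    p_mix <- pi_i * inst$theta$p_r + (1 - pi_i) * inst$theta$p_o
    want <- stats::dmultinom(inst$Y[, 1], prob = p_mix, log = TRUE) +
      stats::dbeta(pi_i, inst$link$a1[1], inst$link$a2[1], log = TRUE)
    expect_equal(got, want, tolerance = 1e-10)
  }

  # a structurally zero mixed proportion at a positive count flags -Inf
  th0 <- mixture_theta(c(0, 1), c(0, 1))
  expect_identical(joint_log_density(c(2, 3), 0.4, th0, 1, 1), -Inf)

  # under p_r = p_o the value no longer depends on pi through the counts
  thn <- mixture_theta(c(.3, .7), c(.3, .7))
  base <- function(t) joint_log_density(c(4, 6), t, thn, 1, 1)
  expect_equal(base(0.2), base(0.8), tolerance = 1e-12)
})

test_that("count moments match the beta-conditioning derivation", {
  # equal compositions collapse to the multinomial margin
  m <- moments_y(100, a1 = 2, a2 = 3, p_r_g = 0.3, p_o_g = 0.3)
  expect_equal(m$mean, 30)
  expect_equal(m$variance, 100 * 0.3 * 0.7)

  # symmetric beta has mean mixing proportion one half
  m <- moments_y(50, a1 = 4, a2 = 4, p_r_g = 0.6, p_o_g = 0.2)
  expect_equal(m$mean, 0.4 * 50)

  # Monte-Carlo oracle from the generative model
  set.seed(17)
  N <- 200; a1 <- 1.4; a2 <- 2.3; p_r_g <- 0.55; p_o_g <- 0.15
  n_mc <- 1e5
  pi_mc <- rbeta(n_mc, a1, a2)
  y_mc <- rbinom(n_mc, N, pi_mc * p_r_g + (1 - pi_mc) * p_o_g)
  m <- moments_y(N, a1, a2, p_r_g, p_o_g)
  se_mean <- sd(y_mc) / sqrt(n_mc)
  expect_lt(abs(mean(y_mc) - m$mean), 3 * se_mean)
  se_var <- sd((y_mc - mean(y_mc))^2) / sqrt(n_mc)
  expect_lt(abs(stats::var(y_mc) - m$variance), 3 * se_var)

  # variance is non-negative over random valid configurations, and
  # collapses to the binomial margin whenever the compositions agree
  set.seed(19)
  for (r in 1:100) {
    a1 <- runif(1, 0.1, 10); a2 <- runif(1, 0.1, 10)
    pr <- runif(1); po <- runif(1); N <- sample(10:5000, 1)
    expect_gte(moments_y(N, a1, a2, pr, po)$variance, 0)
    m_eq <- moments_y(N, a1, a2, po, po)
    expect_equal(m_eq$variance, N * po * (1 - po), tolerance = 1e-9)
  }
})
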