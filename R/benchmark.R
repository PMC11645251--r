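#' Rejection-rate benchmark over a grid of signal strengths
#'
#' Runs the shifted-composition simulation design at each `delta`, applies
#' the requested tests to every replicate and tabulates the fraction of
#' p-values below `alpha`. The `delta = 0` rows estimate the type-I error
#' rate; `delta > 0` rows estimate power at total signal
#' \eqn{t = G\delta^2}. Besides the two model-based tests, a simple baseline
#' is available: per-taxon two-sample t-tests on sample proportions between
#' the stool and reference groups, Bonferroni-adjusted, rejecting the global
#' null when any adjusted p-value falls below `alpha`.
#'
#' @param deltas Numeric vector of per-taxon shifts (0 allowed).
#' @param design A [sim_design()] used as template; its `delta` is replaced
#'   by each grid value (`mode` must be `"shifted_pr"`).
#' @param methods Subset of `c("asymptotic", "permutation", "ttest")`.
#' @param reps Replicates per grid point (default 100).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed; replicate r at every grid point uses sub-seed
#'   `seed + r` so grids are comparable across methods.
#' @param B_asymptotic Null draws for the asymptotic test (default 2000).
#' @param B_permutation Permutations for the permutation test (default 50).
#' @param fit_args,em_args,perm_em_args Argument lists forwarded to
#'   [fit_demix1()], [fit_em()] and the permutation refits.
#' @return A tibble with columns `delta`, `t` (total signal), `method`,
#'   `reps`, `rejection_rate`.
#' @export
benchmark_power <- function(deltas, design,
                            methods = c("asymptotic"),
                            reps = 100, alpha = 0.05, seed = 1,
                            B_asymptotic = 2000, B_permutation = 50,
                            fit_args = list(), em_args = list(),
                            perm_em_args = list(K = 10, M = 20, burnin = 100)) {
  stopifnot(inherits(design, "sim_design"))
  if (design$mode != "shifted_pr") {
    stopf("benchmark_power requires a shifted_pr design")
  }
  methods <- match.arg(methods, c("asymptotic", "permutation", "ttest"),
                       several.ok = TRUE)
  grid <- tidyr::expand_grid(delta = deltas, method = methods)
  res <- purrr::pmap(grid, function(delta, method) {
    des <- sim_design(
      G = design$G, S = design$S, S_r = design$S_r, N = design$N,
      N_r = design$N_r, mode = "shifted_pr", delta = delta,
      beta0 = design$beta0, beta = design$beta, gamma0 = design$gamma0,
      gamma = design$gamma, covariate_mean = design$covariate_mean,
      covariate_sd = design$covariate_sd
    )
    rej <- vapply(seq_len(reps), function(r) {
      sim <- simulate_dataset(des, seed = seed + r)
      p <- switch(
        method,
        asymptotic = {
          tst <- do.call(test_asymptotic,
                         c(list(sim$stool, sim$rectum, sim$covariates,
                                B = B_asymptotic, seed = seed + r),
                           fit_args))
          tst$p_value
        },
        permutation = {
          tst <- do.call(test_permutation,
                         c(list(sim$stool, sim$rectum, sim$covariates,
                                sim$rectum_covariates, B = B_permutation,
                                seed = seed + r, em_args = em_args,
                                perm_em_args = perm_em_args)))
          tst$p_value
        },
        ttest = bonferroni_ttest_pvalue(sim$stool, sim$rectum)
      )
      p < alpha
    }, logical(1L))
    tibble::tibble(delta = delta, t = des$G * delta^2, method = method,
                   reps = reps, rejection_rate = mean(rej))
  })
  dplyr::bind_rows(res)
}

# Baseline: per-taxon two-sample t-tests on sample proportions,
# Bonferroni-combined into one global p-value.
bonferroni_ttest_pvalue <- function(stool, rectum) {
  ps <- sweep(stool, 2L, colSums(stool), "/")
  pr <- sweep(rectum, 2L, colSums(rectum), "/")
  pvals <- vapply(seq_len(nrow(ps)), function(g) {
    tryCatch(t.test(ps[g, ], pr[g, ])$p.value, error = function(e) 1)
  }, numeric(1L))
  min(p.adjust(pvals, "bonferroni"))
}
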