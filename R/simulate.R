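#' Softmax map from unconstrained reals to the simplex
#'
#' \eqn{p_g = e^{u_g} / \sum_k e^{u_k}}, computed with max-subtraction for
#' numerical stability. The map is invariant to adding a constant to `u`.
#'
#' @param u Finite real vector.
#' @return A strictly positive simplex vector of the same length.
#' @export
softmax_reparam <- function(u) {
  if (any(!is.finite(u))) stopf("u must be finite")
  e <- exp(u - max(u))
  e / sum(e)
}

#' Canonical "other locations" composition used by the simulation designs
#'
#' Builds the unconstrained vector `u` with its first `G - 1` entries evenly
#' spaced on `[-1, 1]` and the last entry equal to minus their sum, then maps
#' it to the simplex with [softmax_reparam()]. For `G = 2` the one-point
#' "evenly spaced" grid is taken as the left endpoint `-1`.
#'
#' @param G Number of taxa (at least 2).
#' @return A simplex vector of length `G`.
#' @export
#'
#' @examples
#' round(make_true_po(5), 3)  # 0.059 0.116 0.225 0.439 0.161
make_true_po <- function(G) {
  G <- as.integer(G)
  if (G < 2L) stopf("G must be at least 2")
  u <- if (G == 2L) -1 else seq(-1, 1, length.out = G - 1L)
  softmax_reparam(c(u, -sum(u)))
}

#' Shift a composition symmetrically to create a differential signal
#'
#' Adds `delta` to the first half of the taxa and subtracts it from the
#' second half, so the result stays on the simplex; the total signal is
#' \eqn{\|p^{(r)} - p^{(o)}\|_2^2 = G\delta^2}.
#'
#' @param p_o Simplex vector of even length.
#' @param delta Non-negative shift, smaller than every entry of the second
#'   half of `p_o`.
#' @return The shifted simplex vector.
#' @export
make_shifted_pr <- function(p_o, delta) {
  assert_probability_vector(p_o, "p_o")
  G <- length(p_o)
  if (delta < 0) stopf("delta must be non-negative")
  if (delta > 0 && G %% 2L != 0L) {
    stopf("the +/- delta split requires an even number of taxa")
  }
  half <- G %/% 2L
  p_r <- p_o + c(rep(delta, half), rep(-delta, G - half))
  if (any(p_r < 0) || any(p_r > 1)) {
    stopf("delta = %g pushes the shifted composition off the simplex", delta)
  }
  p_r
}

#' Describe a synthetic-data generating configuration
#'
#' Two published designs are supported. `mode = "uniform_pr"` is the
#' estimation design: the reference composition is uniform `1/G`, the other
#' locations follow [make_true_po()], link coefficients
#' `(0.1, 0.1, 0.2, 0.1)`, and a standard-normal covariate.
#' `mode = "shifted_pr"` is the testing design: the reference composition is
#' [make_shifted_pr()] of the softmax composition with per-taxon signal
#' `delta`, link coefficients `(0.1, 0.1, 0.7, 0.2)`, and covariates drawn
#' from Normal(10, sd 0.1).
#'
#' @param G Number of taxa.
#' @param S,S_r Numbers of stool and reference (rectum) samples.
#' @param N,N_r Library sizes for stool and reference samples (every sample
#'   in a group shares the group's depth).
#' @param mode `"uniform_pr"` or `"shifted_pr"`.
#' @param delta Per-taxon shift for `"shifted_pr"` (0 gives the global null).
#' @param beta0,beta,gamma0,gamma Link coefficients; defaults follow `mode`.
#' @param covariate_mean,covariate_sd Normal law of the single covariate;
#'   defaults follow `mode`.
#'
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(G, S = 100, S_r = 100, N = 5000, N_r = N,
                       mode = c("uniform_pr", "shifted_pr"), delta = 0,
                       beta0 = NULL, beta = NULL, gamma0 = NULL, gamma = NULL,
                       covariate_mean = NULL, covariate_sd = NULL) {
  mode <- match.arg(mode)
  defaults <- if (mode == "uniform_pr") {
    list(beta0 = 0.1, beta = 0.1, gamma0 = 0.2, gamma = 0.1,
         covariate_mean = 0, covariate_sd = 1)
  } else {
    list(beta0 = 0.1, beta = 0.1, gamma0 = 0.7, gamma = 0.2,
         covariate_mean = 10, covariate_sd = 0.1)
  }
  design <- list(
    G = as.integer(G), S = as.integer(S), S_r = as.integer(S_r),
    N = as.integer(N), N_r = as.integer(N_r), mode = mode,
    delta = as.numeric(delta),
    beta0 = beta0 %||% defaults$beta0, beta = beta %||% defaults$beta,
    gamma0 = gamma0 %||% defaults$gamma0, gamma = gamma %||% defaults$gamma,
    covariate_mean = covariate_mean %||% defaults$covariate_mean,
    covariate_sd = covariate_sd %||% defaults$covariate_sd
  )
  if (design$G < 2L) stopf("G must be at least 2")
  if (design$delta < 0) stopf("delta must be non-negative")
  if (design$mode == "uniform_pr" && design$delta != 0) {
    stopf("delta only applies to the shifted_pr design")
  }
  p_o <- make_true_po(design$G)
  p_r <- if (mode == "uniform_pr") rep(1 / design$G, design$G)
         else make_shifted_pr(p_o, design$delta)
  design$truth <- mixture_theta(
    p_r = p_r, p_o = p_o, beta0 = design$beta0, beta = design$beta,
    gamma0 = design$gamma0, gamma = design$gamma
  )
  structure(design, class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf(
    "<sim_design> mode = %s, G = %d, S = %d, S_r = %d, N = %d, N_r = %d, delta = %g\n",
    x$mode, x$G, x$S, x$S_r, x$N, x$N_r, x$delta))
  invisible(x)
}

#' Simulate a paired rectum/stool dataset
#'
#' Draws reference counts i.i.d. Multinomial(`N_r`, `p_r`); one normal
#' covariate per stool sample; latent mixing proportions
#' \eqn{\pi_i \sim \mathrm{Beta}(a_{1,i}, a_{2,i})} through the
#' beta-regression links; and stool counts Multinomial(`N`,
#' \eqn{\pi_i p^{(r)} + (1-\pi_i) p^{(o)}}). Fully reproducible from `seed`.
#'
#' @param design A [sim_design()].
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#'
#' @return A list of class `sim_output` with elements `rectum` and `stool`
#'   (taxa-by-samples count matrices), `covariates` (samples x 1 matrix,
#'   stool), `rectum_covariates` (samples x 1 matrix, drawn from the same
#'   law; used only by the permutation test), `latent_pi` (true mixing
#'   proportions, kept for validation, never exported as observed data) and
#'   `truth` (the generating [mixture_theta()]).
#' @export
simulate_dataset <- function(design, seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  with_seed_(seed, {
    th <- design$truth
    G <- design$G
    taxa <- paste0("taxon", seq_len(G))
    rectum <- rmultinom(design$S_r, design$N_r, th$p_r)
    dimnames(rectum) <- list(taxa, paste0("rectum", seq_len(design$S_r)))
    x <- matrix(rnorm(design$S, design$covariate_mean, design$covariate_sd),
                ncol = 1L, dimnames = list(paste0("stool", seq_len(design$S)),
                                           "x1"))
    x_r <- matrix(rnorm(design$S_r, design$covariate_mean, design$covariate_sd),
                  ncol = 1L,
                  dimnames = list(colnames(rectum), "x1"))
    link <- link_mu_phi(x, th)
    pi_i <- rbeta(design$S, link$a1, link$a2)
    stool <- vapply(seq_len(design$S), function(i) {
      rmultinom(1L, design$N, pi_i[i] * th$p_r + (1 - pi_i[i]) * th$p_o)[, 1L]
    }, numeric(G))
    dimnames(stool) <- list(taxa, rownames(x))
    structure(
      list(rectum = rectum, stool = stool, covariates = x,
           rectum_covariates = x_r, latent_pi = pi_i, truth = th,
           design = design),
      class = "sim_output"
    )
  })
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output> %d taxa; %d rectum and %d stool samples\n",
              nrow(x$rectum), ncol(x$rectum), ncol(x$stool)))
  invisible(x)
}
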