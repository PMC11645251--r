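# Permutation test of H0: p(o) = p(r), compatible with the EM estimator.
# Whole samples travel between groups together with their covariates, so
# reference-sample covariates are required even though the reference model
# itself ignores them.

#' Randomly repartition pooled samples into permuted rectum/stool groups
#'
#' Pools the `S_r + S` samples (with their covariates), draws `S` of them
#' without replacement as the permuted stool set and leaves the remaining
#' `S_r` as the permuted rectum set, preserving the group sizes.
#'
#' @param rectum,stool Taxa-by-samples count matrices with identical taxa.
#' @param rectum_X,stool_X Covariate matrices (samples x d) for each group.
#' @param seed Integer seed or `NULL`.
#' @return A list with `rectum`, `rectum_X`, `stool`, `stool_X`.
#' @export
permute_split <- function(rectum, stool, rectum_X, stool_X, seed = NULL) {
  rectum <- as_count_matrix(rectum)
  stool <- as_count_matrix(stool)
  if (!identical(rownames(rectum), rownames(stool))) {
    stopf("rectum and stool must share the same taxa in the same order")
  }
  rectum_X <- as_covariate_matrix(rectum_X, ncol(rectum))
  stool_X <- as_covariate_matrix(stool_X, ncol(stool))
  if (ncol(rectum_X) != ncol(stool_X)) {
    stopf("covariate dimensions differ between groups")
  }
  S_r <- ncol(rectum); S <- ncol(stool)
  pooled <- cbind(rectum, stool)
  pooled_X <- rbind(rectum_X, stool_X)
  with_seed_(seed, {
    stool_idx <- sample.int(S_r + S, S)
    list(
      rectum = pooled[, -stool_idx, drop = FALSE],
      rectum_X = pooled_X[-stool_idx, , drop = FALSE],
      stool = pooled[, stool_idx, drop = FALSE],
      stool_X = pooled_X[stool_idx, , drop = FALSE]
    )
  })
}

#' Permutation global test of compositional equality
#'
#' Computes the observed statistic \eqn{\hat T = \|\hat p^{(r)} -
#' \hat p^{(o)}\|^2} from the unpermuted data (pooled reference proportions
#' plus an EM fit of the stool model), then, for each of `B` permutations,
#' repartitions the pooled samples with [permute_split()], re-estimates both
#' compositions on the permuted groups (pooled proportions on the permuted
#' rectum set; [fit_em()] on the permuted stool set with its covariates) and
#' forms the permuted statistic. The p-value uses the add-one formula, so it
#' is never below \eqn{1/(1+B)}. A permutation whose EM refit fails is
#' redrawn (up to `max_retries` in total, with a message).
#'
#' @param stool,rectum Taxa-by-samples count matrices with identical taxa.
#' @param stool_X,rectum_X Covariate matrices for the two groups.
#' @param B Number of permutations (default 100).
#' @param seed Integer seed or `NULL`.
#' @param fit Optional precomputed EM `demix_fit` for the observed stool
#'   data.
#' @param em_args List of arguments passed to [fit_em()] for the observed
#'   fit.
#' @param perm_em_args List of arguments for the permutation refits; the
#'   default is a faster profile (`K = 10`, `M = 20`, `burnin = 100`)
#'   because each permutation repeats the whole EM.
#' @param max_retries Total redraw budget for failed refits (default 10).
#' @return A `demix_test` object with `method = "permutation"`; the permuted
#'   statistics are in `null_draws` and the observed EM fit in `fit`.
#' @export
test_permutation <- function(stool, rectum, stool_X = NULL, rectum_X = NULL,
                             B = 100, seed = NULL, fit = NULL,
                             em_args = list(),
                             perm_em_args = list(K = 10, M = 20, burnin = 100),
                             max_retries = 10) {
  stool <- as_count_matrix(stool)
  rectum <- as_count_matrix(rectum)
  if (!identical(rownames(stool), rownames(rectum))) {
    stopf("stool and rectum must share the same taxa in the same order")
  }
  stool_X <- as_covariate_matrix(stool_X, ncol(stool))
  rectum_X <- as_covariate_matrix(rectum_X, ncol(rectum))

  p_hat_r <- estimate_p_r(rectum)
  if (is.null(fit)) {
    fit <- do.call(fit_em, c(list(stool, stool_X, p_hat_r), em_args))
  }
  T_obs <- test_stat(p_hat_r, fit$theta_hat$p_o)

  with_seed_(seed, {
    T_perm <- numeric(B)
    retries <- 0L
    b <- 0L
    while (b < B) {
      perm <- permute_split(rectum, stool, rectum_X, stool_X)
      res <- tryCatch({
        p_r_b <- estimate_p_r(perm$rectum)
        fit_b <- do.call(fit_em,
                         c(list(perm$stool, perm$stool_X, p_r_b),
                           perm_em_args))
        test_stat(p_r_b, fit_b$theta_hat$p_o)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        retries <- retries + 1L
        if (retries > max_retries) {
          stopf("too many failed EM refits during permutation (%d); last: %s",
                retries, conditionMessage(res))
        }
        message("test_permutation: redrawing a failed permutation (",
                conditionMessage(res), ")")
        next
      }
      b <- b + 1L
      T_perm[b] <- res
    }
    out <- new_demix_test(T_obs, mc_pvalue(T_obs, T_perm), B, "permutation",
                          T_perm)
    out$fit <- fit
    out
  })
}
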