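#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted mixture model
#'
#' One row per model quantity: the estimated other-location composition, the
#' plug-in reference composition and the link coefficients.
#'
#' @param x A `demix_fit` from [fit_demix1()] or [fit_em()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `taxon`, `estimate`.
#' @export
tidy.demix_fit <- function(x, ...) {
  th <- x$theta_hat
  taxa <- x$taxa %||% paste0("taxon", seq_along(th$p_o))
  d <- length(th$beta)
  coef_terms <- c("beta0", if (d) paste0("beta", seq_len(d)),
                  "gamma0", if (d) paste0("gamma", seq_len(d)))
  dplyr::bind_rows(
    tibble::tibble(term = "p_o", taxon = taxa, estimate = unname(th$p_o)),
    tibble::tibble(term = "p_r", taxon = taxa, estimate = unname(th$p_r)),
    tibble::tibble(term = coef_terms, taxon = NA_character_,
                   estimate = c(th$beta0, th$beta, th$gamma0, th$gamma))
  )
}

#' One-row summary of a fitted mixture model
#'
#' @param x A `demix_fit`.
#' @param ... Unused.
#' @return A tibble with `method`, `logLik`, `n_iter`, `converged`,
#'   `n_taxa`, `statistic` (the squared distance between the two estimated
#'   compositions).
#' @export
glance.demix_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    logLik = x$loglik,
    n_iter = x$n_outer,
    converged = x$converged,
    n_taxa = length(x$theta_hat$p_o),
    statistic = test_stat(x$theta_hat$p_r, x$theta_hat$p_o)
  )
}

#' Tidy a global test result
#'
#' @param x A `demix_test` from [test_asymptotic()] or [test_permutation()].
#' @param ... Unused.
#' @return A one-row tibble with `method`, `statistic`, `p_value`, `B`.
#' @export
tidy.demix_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p_value = x$p_value, B = x$B)
}

#' @rdname tidy.demix_test
#' @export
glance.demix_test <- function(x, ...) tidy.demix_test(x)
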