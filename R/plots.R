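#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_histogram
#'   geom_vline geom_line geom_point geom_hline labs facet_wrap
#'   position_dodge
#' @export
ggplot2::autoplot

#' Plot the two estimated compositions side by side
#'
#' Dodged bars of the plug-in reference composition and the estimated
#' other-location composition, one pair per taxon.
#'
#' @param object A `demix_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.demix_fit <- function(object, ...) {
  df <- tidy(object)
  df <- dplyr::filter(df, .data$term %in% c("p_r", "p_o"))
  df$location <- ifelse(df$term == "p_r", "reference (rectum)",
                        "other GI locations")
  ggplot(df, aes(x = .data$taxon, y = .data$estimate,
                 fill = .data$location)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "estimated proportion", fill = NULL,
         title = sprintf("Estimated compositions (%s)", object$method))
}

#' Plot a test's null distribution and observed statistic
#'
#' Histogram of the simulated (or permuted) null statistics with the
#' observed statistic marked by a vertical line.
#'
#' @param object A `demix_test`.
#' @param bins Histogram bins (default 40).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.demix_test <- function(object, bins = 40, ...) {
  df <- tibble::tibble(T_null = object$null_draws)
  ggplot(df, aes(x = .data$T_null)) +
    geom_histogram(bins = bins) +
    geom_vline(xintercept = object$statistic, colour = "red") +
    labs(x = "null statistic", y = "count",
         title = sprintf("%s test: T = %.3g, p = %.3g (B = %d)",
                         object$method, object$statistic, object$p_value,
                         object$B))
}

#' Power curves from a rejection-rate benchmark
#'
#' @param results Output of [benchmark_power()].
#' @param alpha Significance level to mark with a dashed line (default
#'   0.05).
#' @return A ggplot object.
#' @export
plot_power_curves <- function(results, alpha = 0.05) {
  ggplot(results, aes(x = .data$t, y = .data$rejection_rate,
                      colour = .data$method)) +
    geom_line() + geom_point() +
    geom_hline(yintercept = alpha, linetype = "dashed") +
    labs(x = expression(paste("total signal  ", t == G * delta^2)),
         y = "rejection rate", colour = NULL)
}
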