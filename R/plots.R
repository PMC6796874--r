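#' MA plot of a comparison, colored by significance
#'
#' @param result A `ComparisonResult`.
#' @param alpha Adjusted-P cutoff used for coloring; default 0.05.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `result`.
#' @export
plot_ma <- function(result, alpha = 0.05, ...) {
  stopifnot(inherits(result, "ComparisonResult"))
  sig <- result$P_adj < alpha
  graphics::plot(result$A, result$M,
                 col = ifelse(sig, "firebrick", grDevices::grey(0.6, 0.5)),
                 pch = 16, cex = 0.4, xlab = "A (mean log2 intensity)",
                 ylab = "M (log2 ratio)", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(result)
}

#' Window variances and the fitted exponential variance function
#'
#' @param x A `VarianceModel`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.VarianceModel <- function(x, ...) {
  est <- x$window_estimates
  use <- !est$degenerate & est$sigma2 > 0
  graphics::plot(est$mean_A[use], est$sigma2[use], log = "y", pch = 16,
                 xlab = "window mean A", ylab = "window variance",
                 ...)
  aa <- seq(min(est$mean_A[use]), max(est$mean_A[use]), length.out = 200)
  graphics::lines(aa, exp(x$theta1 + x$theta2 * aa), col = "firebrick")
  invisible(x)
}

#' Rescaled ordered-ratio diagnostic plot
#'
#' Plots the across-window mean of the rescaled ordered log2 ratios at
#' each rank against the theoretical normal quantile, with error bars of
#' one SD and the reference line y = x. Under the null the middle ranks
#' follow the line; divergence at the extremes marks differential
#' proteins.
#'
#' @param summary Output of [rescaled_qq_summary()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `summary`.
#' @export
plot_rescaled_qq <- function(summary, ...) {
  graphics::plot(summary$q, summary$mean, pch = 16, cex = 0.4,
                 xlab = "theoretical quantile",
                 ylab = "rescaled ordered log2 ratio (mean across windows)",
                 ...)
  graphics::segments(summary$q, summary$mean - summary$sd,
                     summary$q, summary$mean + summary$sd,
                     col = grDevices::grey(0.5, 0.5))
  graphics::abline(0, 1, col = "firebrick")
  invisible(summary)
}
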