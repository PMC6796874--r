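#' Compare two proteomic profiles
#'
#' The full single-run pipeline: trimmed-total normalization, MA transform,
#' sliding-window QQ regression, global exponential variance-function fit,
#' and per-protein significance. Each protein's null variance is the global
#' function evaluated at its own mean log2 intensity (plus the
#' across-window intercept variance in stringent mode).
#'
#' @param pair A `ConditionPair`, e.g. from [combine_channels()] or
#'   [simulate_pair()].
#' @param normalize Apply [normalize_pair()] first? Default `TRUE`.
#' @param trim_L Trimming multiplier for normalization.
#' @param window_size,step,middle_fraction,qq_a Passed to
#'   [window_config()].
#' @param stringent Use the stringent null variance
#'   `Psi(theta, A) + sigma_mu_sq`? Default `FALSE`.
#' @return A `ComparisonResult` data frame with columns `protein_id`, `A`,
#'   `M`, `sigma2`, `Z`, `P`, `P_adj`, and attributes `variance_model`,
#'   `normalization`, `config`, `stringent`.
#' @examples
#' sim <- simulate_pair(simulation_config(n_proteins = 1200, seed = 1))
#' res <- map_compare(sim$pair)
#' head(res[order(res$P), ])
#' @export
map_compare <- function(pair, normalize = TRUE, trim_L = 1.5,
                        window_size = 400, step = 100,
                        middle_fraction = 0.5, qq_a = 0.3175,
                        stringent = FALSE) {
  stopifnot(inherits(pair, "ConditionPair"))
  cfg <- window_config(window_size, step, middle_fraction, qq_a)
  norm_summary <- NULL
  if (normalize) {
    norm <- normalize_pair(pair, L = trim_L)
    pair <- norm$pair
    norm_summary <- norm$summary
  }
  points <- compute_ma(pair)
  model <- build_error_model(points, cfg)
  sigma2 <- suppressMessages(
    if (stringent) stringent_sigma2(points$A, model)
    else predict(model, points$A))
  res <- data.frame(protein_id = points$protein_id,
                    A = points$A, M = points$M, sigma2 = sigma2,
                    Z = z_statistic(points$M, sigma2),
                    P = protein_pvalue(points$M, sigma2),
                    stringsAsFactors = FALSE)
  res$P_adj <- bh_adjust(res$P)
  structure(res,
            variance_model = model,
            normalization = norm_summary,
            config = cfg,
            stringent = stringent,
            class = c("ComparisonResult", "data.frame"))
}

#' @export
print.ComparisonResult <- function(x, alpha = 0.05, ...) {
  model <- attr(x, "variance_model")
  cat(sprintf("ComparisonResult: %d proteins%s\n", nrow(x),
              if (isTRUE(attr(x, "stringent"))) " (stringent mode)" else ""))
  if (!is.null(model)) {
    cat(sprintf("  variance function: exp(%.4f %+.4f * A), fit R^2 = %.4f\n",
                model$theta1, model$theta2, model$fit_r_squared))
  }
  cat(sprintf("  proteins with adjusted P < %g: %d\n",
              alpha, sum(x$P_adj < alpha)))
  invisible(x)
}

#' Integrate per-run comparisons across replicates
#'
#' Combines [map_compare()] results from multiple MS runs (biological
#' replicates): per-protein detection count k, best and second-best
#' P-values, Stouffer-style average Z with its two-tailed P, and — when at
#' least two runs are given — permutation-based FDR estimates for the
#' second-best-P and average-Z rankings.
#'
#' @param results List of `ComparisonResult` objects (or data frames with
#'   columns `protein_id`, `Z`, `P`).
#' @param n_permutations Number of permutations for the FDR estimates; set
#'   to 0 to skip them. Default 1000.
#' @param seed Integer RNG seed for the permutations (required when
#'   `n_permutations > 0`).
#' @return An `IntegrationResult` data frame.
#' @export
map_integrate <- function(results, n_permutations = 1000, seed = NULL) {
  out <- rank_statistics(results)
  if (n_permutations > 0 && length(results) >= 2) {
    if (is.null(seed)) stop("'seed' is required for the permutation FDR")
    f1 <- permutation_fdr(results, statistic = "second_best_p",
                          n_permutations = n_permutations, seed = seed)
    f2 <- permutation_fdr(results, statistic = "avg_z",
                          n_permutations = n_permutations, seed = seed + 1L)
    out$fdr_second_best <- f1$fdr[match(out$protein_id, f1$protein_id)]
    out$fdr_avg_z <- f2$fdr[match(out$protein_id, f2$protein_id)]
  }
  out
}
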