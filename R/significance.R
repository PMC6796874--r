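#' Two-tailed P-value for a protein's log2 ratio
#'
#' Probability of observing a log2 ratio at least as large in magnitude as
#' `|M|` under the null error distribution `N(0, sigma2)`:
#' `P = 2 * (1 - Phi(|M| / sigma))`. P-values are floored at the smallest
#' positive double so that downstream `-log10` transforms stay finite.
#'
#' @param M Log2 ratio(s).
#' @param sigma2 Modeled null variance(s), strictly positive; recycled
#'   against `M`.
#' @return P-value(s) in `(0, 1]`.
#' @examples
#' protein_pvalue(0, 1)                       # 1
#' protein_pvalue(qnorm(0.975) * 2, 4)        # 0.05
#' @export
protein_pvalue <- function(M, sigma2) {
  if (any(!is.finite(sigma2)) || any(sigma2 <= 0)) {
    stop("'sigma2' must be strictly positive")
  }
  p <- 2 * stats::pnorm(abs(M) / sqrt(sigma2), lower.tail = FALSE)
  pmax(p, .Machine$double.xmin)
}

#' Z-statistic of a protein's abundance change
#'
#' `Z = M / sigma`, with sigma the modeled null SD at the protein's
#' intensity. Under the null model Z is standard normal irrespective of
#' intensity level, which makes Z comparable across MS runs.
#'
#' @inheritParams protein_pvalue
#' @return Z value(s); `sign(Z) == sign(M)`.
#' @export
z_statistic <- function(M, sigma2) {
  if (any(!is.finite(sigma2)) || any(sigma2 <= 0)) {
    stop("'sigma2' must be strictly positive")
  }
  M / sqrt(sigma2)
}

#' Stringent-mode null variance
#'
#' The window intercepts mu fluctuate around zero because global
#' normalization cannot remove all local bias. The stringent option absorbs
#' that residual bias into the null by adding `sigma_mu_sq` — the variance
#' of mu across all windows — to the modeled variance, so every stringent
#' P-value is at least as large as the default one.
#'
#' @param A Mean log2 intensity value(s).
#' @param model A `VarianceModel`.
#' @return Variance(s) `Psi(theta, A) + sigma_mu_sq`.
#' @export
stringent_sigma2 <- function(A, model) {
  stopifnot(inherits(model, "VarianceModel"))
  predict(model, A) + model$sigma_mu_sq
}

#' Benjamini-Hochberg adjusted P-values
#'
#' Standard step-up adjustment within one comparison, capped at 1 and
#' returned in the input order.
#'
#' @param P Numeric vector of P-values in `(0, 1]`.
#' @return Adjusted P-values, `P_adj >= P` elementwise.
#' @export
bh_adjust <- function(P) {
  if (length(P) == 0) return(numeric(0))
  if (any(!is.finite(P)) || any(P <= 0) || any(P > 1)) {
    stop("P-values must lie in (0, 1]")
  }
  stats::p.adjust(P, method = "BH")
}
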