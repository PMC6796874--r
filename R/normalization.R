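#' Flag high-intensity outlier proteins
#'
#' A protein is an outlier within a profile when its intensity exceeds
#' `Q3 + L * (Q3 - Q1)` (strict inequality), where Q1 and Q3 are the 25th
#' and 75th percentiles of the profile's intensities. Outliers are excluded
#' from the trimmed totals used for normalization but are still normalized
#' and tested downstream.
#'
#' @param intensities Non-empty numeric vector of intensities.
#' @param L Trimming multiplier; the conventional boxplot fence `L = 1.5`
#'   by default.
#' @param quantile_type Percentile convention passed to [stats::quantile()];
#'   default 7 (linear interpolation of order statistics).
#' @return Integer indices of the outliers (possibly empty).
#' @examples
#' detect_outliers(c(1, 2, 3, 4, 100))  # 5
#' @export
detect_outliers <- function(intensities, L = 1.5, quantile_type = 7) {
  if (length(intensities) == 0) stop("'intensities' must be non-empty")
  if (any(!is.finite(intensities))) stop("'intensities' must be finite")
  q <- stats::quantile(intensities, c(0.25, 0.75), names = FALSE,
                       type = quantile_type)
  which(intensities > q[2] + L * (q[2] - q[1]))
}

#' Trimmed-total-intensity normalization of a condition pair
#'
#' Makes the two condition profiles comparable. Outliers are flagged in each
#' profile separately; the trimmed total of each profile is the sum of
#' intensities over proteins flagged in *neither* profile. Each profile's
#' normalization factor is its trimmed total divided by the mean of the two
#' trimmed totals, and every intensity (outliers included) is divided by its
#' profile's factor, so the trimmed totals are exactly equal afterwards.
#'
#' @param pair A `ConditionPair`.
#' @param L Trimming multiplier for [detect_outliers()].
#' @param quantile_type Percentile convention, see [detect_outliers()].
#' @return List with elements `pair` (the normalized `ConditionPair`) and
#'   `summary` (a `NormalizationSummary`).
#' @export
normalize_pair <- function(pair, L = 1.5, quantile_type = 7) {
  stopifnot(inherits(pair, "ConditionPair"))
  if (nrow(pair) == 0) stop("'pair' must be non-empty")
  ia <- pair$intensity_a
  ib <- pair$intensity_b
  out_a <- detect_outliers(ia, L = L, quantile_type = quantile_type)
  out_b <- detect_outliers(ib, L = L, quantile_type = quantile_type)
  excluded <- union(out_a, out_b)
  keep <- setdiff(seq_len(nrow(pair)), excluded)
  if (length(keep) == 0) stop("all proteins flagged as outliers; cannot normalize")
  trimmed <- c(sum(ia[keep]), sum(ib[keep]))
  if (any(trimmed <= 0)) stop("trimmed total intensity is zero")
  factors <- trimmed / mean(trimmed)
  norm <- condition_pair(pair$protein_id,
                         ia / factors[1], ib / factors[2],
                         conditions = attr(pair, "conditions"),
                         n_dropped = attr(pair, "n_dropped"),
                         run_id = attr(pair, "run_id"))
  summary <- structure(list(
    L = L,
    quartiles = rbind(a = stats::quantile(ia, c(0.25, 0.75), names = FALSE,
                                          type = quantile_type),
                      b = stats::quantile(ib, c(0.25, 0.75), names = FALSE,
                                          type = quantile_type)),
    outlier_ids = list(a = pair$protein_id[out_a],
                       b = pair$protein_id[out_b]),
    trimmed_total = trimmed,
    factor = factors
  ), class = "NormalizationSummary")
  list(pair = norm, summary = summary)
}

#' @export
print.NormalizationSummary <- function(x, ...) {
  cat("Trimmed-total-intensity normalization (L =", x$L, ")\n")
  cat(sprintf("  outliers: %d (first profile), %d (second profile)\n",
              length(x$outlier_ids$a), length(x$outlier_ids$b)))
  cat(sprintf("  trimmed totals: %.6g / %.6g; factors: %.6f / %.6f\n",
              x$trimmed_total[1], x$trimmed_total[2],
              x$factor[1], x$factor[2]))
  invisible(x)
}
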