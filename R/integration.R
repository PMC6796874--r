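as_run_frame <- function(r, i) {
  if (!all(c("protein_id", "Z", "P") %in% names(r))) {
    stop("run ", i, " lacks the required columns protein_id, Z, P")
  }
  r
}

run_matrices <- function(results) {
  results <- lapply(seq_along(results), function(i) {
    as_run_frame(results[[i]], i)
  })
  ids <- unique(unlist(lapply(results, `[[`, "protein_id")))
  k <- length(results)
  Z <- P <- matrix(NA_real_, nrow = length(ids), ncol = k,
                   dimnames = list(ids, NULL))
  for (t in seq_len(k)) {
    r <- results[[t]]
    Z[r$protein_id, t] <- r$Z
    P[r$protein_id, t] <- r$P
  }
  list(ids = ids, Z = Z, P = P, detected = !is.na(Z))
}

# second smallest per row of a matrix with NA = not detected
row_second_smallest <- function(P) {
  work <- P
  work[is.na(work)] <- Inf
  first_idx <- max.col(-work, ties.method = "first")
  work[cbind(seq_len(nrow(work)), first_idx)] <- Inf
  second <- do.call(pmin, as.data.frame(work))
  second[!is.finite(second)] <- NA_real_
  second
}

#' Combine per-run statistics into integration rank statistics
#'
#' For each protein across k runs: the number of comparisons in which it
#' was detected, the best (smallest) and second-best P-values, and the
#' Stouffer-style average Z-statistic `Z_hat = sum(Z_t) / sqrt(k)` over the
#' runs where it was detected, with its two-tailed standard-normal P-value
#' and BH adjustment. The second-best P is defined only for proteins
#' detected in at least two runs; single-run proteins are retained and
#' flagged by `k = 1`, not dropped.
#'
#' @param results List of `ComparisonResult` objects (one per MS run).
#' @return An `IntegrationResult` data frame with columns `protein_id`,
#'   `k`, `best_P`, `second_best_P`, `avg_Z`, `avg_Z_P`, `avg_Z_P_adj`.
#' @export
rank_statistics <- function(results) {
  if (!is.list(results) || length(results) == 0) {
    stop("'results' must be a non-empty list of per-run results")
  }
  mats <- run_matrices(results)
  k <- rowSums(mats$detected)
  avg_z <- rowSums(mats$Z, na.rm = TRUE) / sqrt(k)
  best <- suppressWarnings(apply(mats$P, 1, min, na.rm = TRUE))
  out <- data.frame(protein_id = mats$ids,
                    k = as.integer(k),
                    best_P = best,
                    second_best_P = row_second_smallest(mats$P),
                    avg_Z = avg_z,
                    avg_Z_P = avg_z_pvalue(avg_z),
                    stringsAsFactors = FALSE)
  out$avg_Z_P_adj <- bh_adjust(out$avg_Z_P)
  structure(out, n_runs = length(results),
            class = c("IntegrationResult", "data.frame"))
}

#' Two-tailed P-value of an average Z-statistic
#'
#' Under the null the average Z over k runs is standard normal, so
#' `P = 2 * (1 - Phi(|Z_hat|))`, floored at the smallest positive double.
#'
#' @param z_hat Average Z value(s).
#' @return P-value(s) in `(0, 1]`.
#' @export
avg_z_pvalue <- function(z_hat) {
  if (any(!is.finite(z_hat))) stop("'z_hat' must be finite")
  pmax(2 * stats::pnorm(abs(z_hat), lower.tail = FALSE),
       .Machine$double.xmin)
}

#' Resampling-based FDR for an integrated statistic
#'
#' Estimates the false discovery rate of declaring proteins significant at
#' each observed value of an integrated statistic, by repeatedly
#' generating null copies of the statistic over the observed detection
#' pattern and comparing expected null exceedance counts with observed
#' counts.
#'
#' Null copies are drawn from the error model's own null hypothesis: for a
#' non-differential protein the per-run Z-statistic is standard normal,
#' and its per-run P-value uniform on (0, 1), independently across runs.
#' Each of the `n_permutations` rounds redraws every detected (protein,
#' run) cell from that null — Z from N(0, 1) for `"avg_z"`, P from
#' U(0, 1) for `"second_best_p"` — and recomputes the integrated
#' statistic, preserving each protein's detection count k. Resampling
#' observed values instead (sign flips or run decoupling) contaminates
#' the null with the very proteins whose large changes are being tested,
#' and systematically overestimates the FDR when strong differential
#' proteins are present; drawing from the modeled null avoids that while
#' remaining faithful to the method's error model.
#'
#' At each observed threshold t, `FDR(t) = mean null count at least as
#' extreme as t / observed count at least as extreme as t`, clipped to
#' `[0, 1]` and made monotone (non-decreasing as the threshold is relaxed)
#' by a running minimum from the least to the most significant threshold.
#'
#' @param results List of at least two per-run `ComparisonResult` objects.
#' @param statistic `"second_best_p"` (smaller = more significant) or
#'   `"avg_z"` (larger |Z_hat| = more significant).
#' @param n_permutations Number of null resampling rounds, at least 10;
#'   default 1000.
#' @param seed Integer RNG seed (required).
#' @return Data frame with columns `protein_id`, `statistic` (the observed
#'   value), `n_discoveries` (observed count at least as extreme), `fdr`.
#'   Proteins for which the statistic is undefined (k < 2 for the
#'   second-best P) get `NA`.
#' @export
permutation_fdr <- function(results,
                            statistic = c("second_best_p", "avg_z"),
                            n_permutations = 1000, seed) {
  statistic <- match.arg(statistic)
  if (!is.list(results) || length(results) < 2) {
    stop("permutation FDR requires at least 2 runs")
  }
  if (n_permutations < 10) stop("'n_permutations' must be at least 10")
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  set.seed(as.integer(seed))
  mats <- run_matrices(results)
  n <- length(mats$ids)
  k <- rowSums(mats$detected)
  n_cells <- sum(mats$detected)

  if (statistic == "avg_z") {
    obs_score <- abs(rowSums(mats$Z, na.rm = TRUE) / sqrt(k))
    eligible <- rep(TRUE, n)
    draw_null <- function() {
      Zn <- mats$Z
      Zn[mats$detected] <- stats::rnorm(n_cells)
      abs(rowSums(Zn, na.rm = TRUE) / sqrt(k))
    }
  } else {
    eligible <- k >= 2
    if (!any(eligible)) stop("no protein is detected in at least 2 runs")
    obs_val <- row_second_smallest(mats$P)
    obs_score <- -obs_val  # larger score = more significant
    draw_null <- function() {
      Pn <- mats$P
      Pn[mats$detected] <- stats::runif(n_cells)
      -row_second_smallest(Pn)[eligible]
    }
  }
  obs <- obs_score[eligible]
  null_pool <- unlist(lapply(seq_len(n_permutations),
                             function(b) draw_null()))
  null_sorted <- sort(null_pool)
  count_ge <- function(pool_sorted, t) {
    length(pool_sorted) - findInterval(t, pool_sorted, left.open = TRUE)
  }
  obs_sorted <- sort(obs)
  R <- count_ge(obs_sorted, obs)
  V <- count_ge(null_sorted, obs) / n_permutations
  raw <- pmin(V / R, 1)
  # monotone: running minimum from least to most significant threshold
  ord <- order(obs, decreasing = TRUE)
  mono <- raw
  mono[ord] <- rev(cummin(rev(raw[ord])))

  out <- data.frame(protein_id = mats$ids,
                    statistic = NA_real_,
                    n_discoveries = NA_integer_,
                    fdr = NA_real_,
                    stringsAsFactors = FALSE)
  out$statistic[eligible] <- if (statistic == "avg_z") obs else -obs
  out$n_discoveries[eligible] <- R
  out$fdr[eligible] <- mono
  structure(out, statistic = statistic,
            n_permutations = n_permutations, seed = seed)
}

#' Direction-consistency score against an external reference
#'
#' Fraction of detected differential proteins whose direction of abundance
#' change agrees with an external direction reference (e.g. mRNA
#' translation changes from ribosome profiling). Proteins absent from the
#' reference are excluded from both numerator and denominator; only signs
#' are compared, never magnitudes.
#'
#' @param dep_directions Named numeric vector of +1/-1 per differential
#'   protein.
#' @param reference_directions Named numeric vector of +1/-1, e.g. from
#'   [filter_reference_directions()].
#' @return The consistency score in `[0, 1]`, with attributes
#'   `n_consistent` and `n_inconsistent`.
#' @examples
#' consistency_score(c(a = 1, b = -1, c = 1, d = 1),
#'                   c(a = 1, b = -1, c = -1, d = 1, e = 1))  # 0.75
#' @export
consistency_score <- function(dep_directions, reference_directions) {
  check_signs <- function(x, what) {
    if (length(x) == 0 || is.null(names(x)) ||
        !all(x %in% c(-1, 1))) {
      stop("'", what, "' must be a non-empty named vector of +1/-1")
    }
  }
  check_signs(dep_directions, "dep_directions")
  check_signs(reference_directions, "reference_directions")
  shared <- intersect(names(dep_directions), names(reference_directions))
  if (length(shared) == 0) {
    stop("no differential protein overlaps the direction reference")
  }
  agree <- dep_directions[shared] == reference_directions[shared]
  structure(mean(agree),
            n_consistent = sum(agree),
            n_inconsistent = sum(!agree))
}

#' Turn a reference log2-ratio table into directions
#'
#' Drops entries whose |log2 ratio| does not exceed the threshold (too
#' small to call a direction) and maps the rest to the sign of their ratio.
#'
#' @param log2_ratios Named numeric vector of reference log2 ratios.
#' @param threshold Strictly positive magnitude cutoff; default 0.2.
#' @return Named vector of +1/-1 (possibly empty).
#' @export
filter_reference_directions <- function(log2_ratios, threshold = 0.2) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("'threshold' must be a single positive number")
  }
  if (is.null(names(log2_ratios))) stop("'log2_ratios' must be named")
  keep <- abs(log2_ratios) > threshold
  sign(log2_ratios[keep])
}

#' Area under the precision-recall curve of a ranking
#'
#' Average-precision summary of how well a significance ranking recovers a
#' set of known positives; used to compare integrated rankings (second-best
#' P, average Z) against single-run rankings on simulated data.
#'
#' @param score Numeric vector; larger = more significant (pass `-P` for
#'   P-value rankings).
#' @param label Logical vector of true-positive labels, same length.
#' @return Area under the precision-recall curve in `[0, 1]`.
#' @export
precision_recall_auc <- function(score, label) {
  stopifnot(length(score) == length(label), is.logical(label))
  if (!any(label)) stop("no positives in 'label'")
  ord <- order(score, decreasing = TRUE)
  lab <- label[ord]
  tp <- cumsum(lab)
  precision <- tp / seq_along(lab)
  sum(precision[lab]) / sum(label)
}
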