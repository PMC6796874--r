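#' MA transform of a normalized condition pair
#'
#' For protein i with intensities S_i1, S_i2 in the two profiles:
#' `A_i = (log2 S_i1 + log2 S_i2) / 2` (mean log2 intensity) and
#' `M_i = log2(S_i1 / S_i2)` (log2 ratio). The contribution of technical
#' and systematic error to M_i is modeled as N(0, sigma_i^2) with
#' sigma_i^2 an exponential function of A_i.
#'
#' @param pair A (normalized) `ConditionPair` with strictly positive
#'   intensities.
#' @return Data frame with columns `protein_id`, `A`, `M`.
#' @examples
#' p <- condition_pair("P1", 8, 2)
#' compute_ma(p)  # A = 2, M = 2
#' @export
compute_ma <- function(pair) {
  stopifnot(inherits(pair, "ConditionPair"))
  bad <- which(pair$intensity_a <= 0 | pair$intensity_b <= 0)
  if (length(bad) > 0) {
    stop("non-positive intensity for protein(s): ",
         paste(sQuote(pair$protein_id[bad[seq_len(min(5, length(bad)))]]),
               collapse = ", "))
  }
  l1 <- log2(pair$intensity_a)
  l2 <- log2(pair$intensity_b)
  data.frame(protein_id = pair$protein_id,
             A = (l1 + l2) / 2,
             M = l1 - l2,
             stringsAsFactors = FALSE)
}

#' Sliding-window configuration for the error model
#'
#' @param window_size Number of proteins per window (N); default 400.
#' @param step Step size in proteins between window starts; default 100.
#' @param middle_fraction Fraction W of each window's ordered log2 ratios,
#'   selected symmetrically around the median, used for the QQ regression;
#'   default 0.5.
#' @param qq_a Plotting-position constant `a`; default 0.3175.
#' @return A `WindowConfig` list.
#' @export
window_config <- function(window_size = 400, step = 100,
                          middle_fraction = 0.5, qq_a = 0.3175) {
  window_size <- as.integer(window_size)
  step <- as.integer(step)
  if (window_size < 20) {
    stop("'window_size' must be at least 20 proteins")
  }
  if (step < 1 || step > window_size) {
    stop("'step' must be in [1, window_size]")
  }
  if (!(middle_fraction > 0 && middle_fraction <= 1)) {
    stop("'middle_fraction' must be in (0, 1]")
  }
  if (!(qq_a >= 0 && qq_a < 1)) stop("'qq_a' must be in [0, 1)")
  n_sel <- window_size - 2L * ceiling(window_size * (1 - middle_fraction) / 2)
  if (n_sel < 10) {
    stop("middle selection of ", n_sel, " proteins is too small; ",
         "increase 'window_size' or 'middle_fraction'")
  }
  structure(list(window_size = window_size, step = step,
                 middle_fraction = middle_fraction, qq_a = qq_a),
            class = "WindowConfig")
}

#' Sliding windows over proteins ordered by mean intensity
#'
#' Sorts proteins by A (ties broken by M, then identifier, for
#' reproducibility) and returns index windows `[k*step + 1, k*step + N]`
#' scanning left to right. The final window is anchored to the right edge
#' (the last N proteins) so that every protein is covered.
#'
#' @param points Data frame from [compute_ma()].
#' @param cfg A `WindowConfig`.
#' @return List of integer index vectors into the *original* row order of
#'   `points`, each sorted by ascending A; attribute `order` holds the full
#'   A-sort permutation.
#' @export
make_windows <- function(points, cfg = window_config()) {
  n <- nrow(points)
  N <- cfg$window_size
  if (n < N) {
    stop("only ", n, " proteins but window_size = ", N,
         "; choose a smaller window")
  }
  ord <- order(points$A, points$M, points$protein_id)
  starts <- seq.int(0L, n - N, by = cfg$step)
  if (starts[length(starts)] != n - N) starts <- c(starts, n - N)
  windows <- lapply(starts, function(s) ord[(s + 1L):(s + N)])
  attr(windows, "order") <- ord
  attr(windows, "starts") <- starts + 1L
  windows
}

#' Plotting positions for (possibly censored) ordered data
#'
#' Implements the Michael-Schucany product formula for the plotting
#' position of the i-th order statistic of a sample of size `n` when only
#' the order statistics with ranks in `omega` are observed:
#' \deqn{\hat p_i = \frac{n-a+1}{n-2a+1} \prod_{j \in \Omega,\, j \ge i}
#'   \frac{j-a}{j-a+1}}
#' For a complete sample the product telescopes to the familiar
#' `(i - a) / (n - 2a + 1)`. The corresponding theoretical quantile of the
#' standard normal distribution is `qnorm(p)`.
#'
#' @param n Sample size.
#' @param omega Increasing integer vector of observed ranks, a subset of
#'   `1:n`; default the complete sample.
#' @param a Plotting-position constant in `[0, 1)`; default 0.3175.
#' @return Data frame with columns `rank`, `p`, `q`.
#' @examples
#' pp <- plotting_positions(5)
#' all.equal(pp$p, (1:5 - 0.3175) / (5 - 2 * 0.3175 + 1))
#' @export
plotting_positions <- function(n, omega = seq_len(n), a = 0.3175) {
  n <- as.integer(n)
  if (length(omega) == 0) stop("'omega' must be non-empty")
  omega <- as.integer(omega)
  if (is.unsorted(omega, strictly = TRUE) ||
      omega[1] < 1L || omega[length(omega)] > n) {
    stop("'omega' must be a strictly increasing subset of 1:n")
  }
  if (!(a >= 0 && a < 1)) stop("'a' must be in [0, 1)")
  ratio <- (omega - a) / (omega - a + 1)
  suffix <- rev(cumprod(rev(ratio)))
  p <- (n - a + 1) / (n - 2 * a + 1) * suffix
  data.frame(rank = omega, p = p, q = stats::qnorm(p))
}

#' Quantile-quantile regression within one window
#'
#' Orders the window's log2 ratios, assigns each rank its complete-sample
#' plotting position and normal quantile, and fits an ordinary
#' least-squares line `M = mu + sigma * q` through the middle
#' `middle_fraction` of the (M, q) pairs — the ratios assumed to be
#' dominated by non-differential proteins. The slope estimates the error
#' SD for the window; its square is the window's variance estimate.
#'
#' Windows with zero spread or non-positive slope in the selected middle
#' are flagged degenerate (they carry no usable scale information).
#'
#' @param m Numeric vector of the window's log2 ratios.
#' @param cfg A `WindowConfig`; `window_size` is taken from `length(m)`.
#' @return A `WindowEstimate` list: `mu`, `sigma`, `sigma2`, `r_squared`,
#'   `n`, `selected_ranks`, `degenerate`.
#' @export
qq_regression <- function(m, cfg = window_config()) {
  n <- length(m)
  if (n < 20) stop("window of ", n, " ratios is too small (minimum 20)")
  trim <- ceiling(n * (1 - cfg$middle_fraction) / 2)
  sel <- (trim + 1L):(n - trim)
  if (length(sel) < 10) {
    stop("middle selection of ", length(sel), " ratios is too small")
  }
  ms <- sort(m)
  y <- ms[sel]
  q <- plotting_positions(n, a = cfg$qq_a)$q[sel]
  est <- list(n = n, selected_ranks = sel)
  if (stats::sd(y) == 0) {
    est <- c(est, list(mu = mean(y), sigma = 0, sigma2 = 0,
                       r_squared = NA_real_, degenerate = TRUE))
    return(structure(est, class = "WindowEstimate"))
  }
  slope <- stats::cov(y, q) / stats::var(q)
  mu <- mean(y) - slope * mean(q)
  r2 <- stats::cor(y, q)^2
  est <- c(est, list(mu = mu, sigma = slope, sigma2 = slope^2,
                     r_squared = r2, degenerate = slope <= 0))
  structure(est, class = "WindowEstimate")
}

#' Fit the global exponential variance function across windows
#'
#' Least-squares fit of the per-window variance estimates to the
#' exponential model `sigma2 = Psi(theta, A) = exp(theta1 + theta2 * A)`,
#' where A is each window's mean log2 intensity over the proteins selected
#' for its regression.
#'
#' The sampling error of a window's variance estimate is multiplicative —
#' its coefficient of variation is roughly constant across windows — while
#' the variances themselves span orders of magnitude over the intensity
#' range. The default `weighting = "relative"` therefore minimizes the
#' *relative* residuals (inverse-squared-mean weights, the constant-CV
#' quasi-likelihood, fitted as a Gamma GLM with log link); an unweighted
#' fit on the raw variance scale is effectively determined by the handful
#' of low-intensity windows alone and is available as
#' `weighting = "absolute"` (Levenberg-Marquardt, initialized from the OLS
#' fit of `log(sigma2)` on A, which nearly solves the problem already).
#'
#' @param estimates Data frame with one row per window and columns
#'   `mean_A`, `sigma2`, `mu`, `degenerate` (as built by
#'   [build_error_model()]).
#' @param weighting `"relative"` (default) or `"absolute"`, see Details.
#' @return A `VarianceModel`: `theta1`, `theta2`, `fit_r_squared`
#'   (coefficient of determination on the variance scale),
#'   `sigma_mu_sq` (variance of `mu` across all windows, for the stringent
#'   mode), and the `window_estimates` table.
#' @export
fit_variance_function <- function(estimates,
                                  weighting = c("relative", "absolute")) {
  stopifnot(is.data.frame(estimates),
            all(c("mean_A", "sigma2", "mu") %in% names(estimates)))
  weighting <- match.arg(weighting)
  if (is.null(estimates$degenerate)) estimates$degenerate <- FALSE
  usable <- estimates[!estimates$degenerate & estimates$sigma2 > 0, ]
  if (nrow(usable) < 2) {
    stop("need at least 2 non-degenerate windows to fit the variance function")
  }
  x <- usable$mean_A
  y <- usable$sigma2
  if (stats::sd(y) == 0) {
    theta <- c(log(y[1]), 0)
    fitted <- y
  } else if (nrow(usable) == 2) {
    # two parameters, two points: exact interpolation
    t2 <- (log(y[2]) - log(y[1])) / (x[2] - x[1])
    theta <- c(log(y[1]) - t2 * x[1], t2)
    fitted <- exp(theta[1] + theta[2] * x)
  } else if (weighting == "relative") {
    fit <- tryCatch(
      stats::glm(y ~ x, family = stats::Gamma(link = "log"),
                 control = stats::glm.control(epsilon = 1e-10,
                                              maxit = 100)),
      error = function(e) {
        stop("variance-function fit did not converge: ",
             conditionMessage(e))
      })
    theta <- stats::coef(fit)
    fitted <- as.numeric(stats::fitted(fit))
  } else {
    init <- stats::coef(stats::lm(log(y) ~ x))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ exp(t1 + t2 * x),
                        start = list(t1 = init[[1]], t2 = init[[2]]),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-10)),
      error = function(e) {
        stop("variance-function fit did not converge (initializer theta = (",
             signif(init[[1]], 6), ", ", signif(init[[2]], 6), ")): ",
             conditionMessage(e))
      })
    theta <- stats::coef(fit)
    fitted <- stats::fitted(fit)
  }
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum((y - fitted)^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(theta1 = unname(theta[1]), theta2 = unname(theta[2]),
                 fit_r_squared = r2,
                 sigma_mu_sq = stats::var(estimates$mu),
                 A_range = range(x),
                 window_estimates = estimates),
            class = "VarianceModel")
}

#' Evaluate the global variance function
#'
#' Returns `Psi(theta, A) = exp(theta1 + theta2 * A)` for each A. The
#' exponential is globally defined, so values of A outside the range of
#' window means used in the fit are extrapolated directly; a message notes
#' when this happens.
#'
#' @param object A `VarianceModel`.
#' @param A Numeric vector of mean log2 intensities.
#' @param ... Unused.
#' @return Numeric vector of modeled variances.
#' @export
predict.VarianceModel <- function(object, A, ...) {
  rng <- object$A_range
  n_out <- sum(A < rng[1] | A > rng[2])
  if (n_out > 0) {
    message(n_out, " protein(s) outside the fitted A range [",
            signif(rng[1], 4), ", ", signif(rng[2], 4),
            "]; variance function extrapolated")
  }
  exp(object$theta1 + object$theta2 * A)
}

#' @export
print.VarianceModel <- function(x, ...) {
  est <- x$window_estimates
  cat("Intensity-dependent error model sigma^2 = exp(theta1 + theta2 * A)\n")
  cat(sprintf("  theta1 = %.4f, theta2 = %.4f (fit R^2 = %.4f)\n",
              x$theta1, x$theta2, x$fit_r_squared))
  cat(sprintf("  windows: %d (%d degenerate); QQ-regression R^2 range %.4f-%.4f\n",
              nrow(est), sum(est$degenerate),
              min(est$r_squared, na.rm = TRUE),
              max(est$r_squared, na.rm = TRUE)))
  cat(sprintf("  sigma_mu^2 (across-window variance of mu) = %.3g\n",
              x$sigma_mu_sq))
  invisible(x)
}

#' Build the error model from MA points
#'
#' Runs the step-by-step regression: sliding windows over proteins ordered
#' by A, one QQ regression per window, then the global exponential
#' variance-function fit. Degenerate windows are excluded from the fit with
#' a warning; the run aborts if more than 20% of windows are degenerate.
#'
#' @param points Data frame from [compute_ma()].
#' @param cfg A `WindowConfig`.
#' @param weighting Passed to [fit_variance_function()].
#' @return A `VarianceModel`; its `A_range` covers all proteins seen, so
#'   [predict.VarianceModel()] only reports extrapolation for genuinely
#'   new intensity values.
#' @export
build_error_model <- function(points, cfg = window_config(),
                              weighting = c("relative", "absolute")) {
  windows <- make_windows(points, cfg)
  rows <- lapply(seq_along(windows), function(w) {
    idx <- windows[[w]]
    est <- qq_regression(points$M[idx], cfg)
    data.frame(window = w,
               start = attr(windows, "starts")[w],
               mean_A = mean(points$A[idx][est$selected_ranks]),
               mu = est$mu, sigma = est$sigma, sigma2 = est$sigma2,
               r_squared = est$r_squared, degenerate = est$degenerate)
  })
  estimates <- do.call(rbind, rows)
  n_degen <- sum(estimates$degenerate)
  if (n_degen > 0) {
    warning(n_degen, " degenerate window(s) excluded from the variance fit")
  }
  if (n_degen > 0.2 * nrow(estimates)) {
    stop(n_degen, " of ", nrow(estimates), " windows are degenerate; ",
         "the profiles do not support the error model")
  }
  model <- fit_variance_function(estimates, weighting = weighting)
  model$A_range <- range(points$A)
  model
}

#' Rescaled ordered-ratio summary across windows
#'
#' Diagnostic behind the rescaled QQ plot: within each (full-size,
#' non-degenerate) window the ordered log2 ratios are divided by that
#' window's estimated sigma; the mean and SD of the rescaled values at each
#' rank are then taken across windows and paired with the complete-sample
#' normal quantile for that rank. Under the null model the middle ranks lie
#' on the line y = x; systematic departure at the extreme ranks indicates
#' differential proteins (or, when comparing technical replicates, outlier
#' measurements).
#'
#' @param points Data frame from [compute_ma()].
#' @param model A `VarianceModel` from [build_error_model()].
#' @param cfg The `WindowConfig` used to build the model.
#' @return Data frame with columns `rank`, `q`, `mean`, `sd`, and attribute
#'   `n_windows`.
#' @export
rescaled_qq_summary <- function(points, model, cfg = window_config()) {
  windows <- make_windows(points, cfg)
  est <- model$window_estimates
  keep <- which(!est$degenerate &
                  lengths(windows) == cfg$window_size)
  n_skipped <- length(windows) - length(keep)
  if (n_skipped > 0) {
    message(n_skipped, " window(s) excluded from the rescaled summary")
  }
  if (length(keep) == 0) stop("no usable windows for the rescaled summary")
  rescaled <- vapply(keep, function(w) {
    sort(points$M[windows[[w]]]) / est$sigma[w]
  }, numeric(cfg$window_size))
  q <- plotting_positions(cfg$window_size, a = cfg$qq_a)$q
  sds <- if (length(keep) == 1) {
    rep(0, cfg$window_size)
  } else {
    apply(rescaled, 1, stats::sd)
  }
  structure(
    data.frame(rank = seq_len(cfg$window_size),
               q = q,
               mean = rowMeans(rescaled),
               sd = sds),
    n_windows = length(keep))
}
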