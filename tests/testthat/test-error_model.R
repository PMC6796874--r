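test_that("MA transform matches its exact-powers-of-two cases", {
  pair <- condition_pair(c("p1", "p2", "p3"), c(8, 7, 1), c(2, 7, 4))
  ma <- compute_ma(pair)
  expect_equal(ma$A, c(2, log2(7), 1))
  expect_equal(ma$M, c(2, 0, -2))
  expect_error(compute_ma(structure(
    data.frame(protein_id = "p1", intensity_a = 0, intensity_b = 1),
    class = c("ConditionPair", "data.frame"))), "p1")
})

test_that("windows scan left to right with a right-anchored final window", {
  pts <- data.frame(protein_id = sprintf("P%04d", 1:1000),
                    A = seq_len(1000) / 10, M = 0)
  w <- make_windows(pts, window_config(400, 100))
  expect_length(w, 7)
  expect_equal(attr(w, "starts"), seq(1, 601, by = 100))
  expect_true(all(lengths(w) == 400))

  # exactly one window at the boundary
  w1 <- make_windows(pts[1:400, ], window_config(400, 100))
  expect_length(w1, 1)

  # 950 points: the last window is anchored to [551, 950]
  w950 <- make_windows(pts[1:950, ], window_config(400, 100))
  expect_equal(attr(w950, "starts"), c(seq(1, 501, by = 100), 551))
  # coverage: every protein falls in at least one window
  expect_setequal(unique(unlist(w950)), 1:950)

  expect_error(make_windows(pts[1:100, ], window_config(400, 100)),
               "smaller window")
})

test_that("windows are index ranges on the A-sorted order", {
  set.seed(41)
  pts <- data.frame(protein_id = sprintf("P%04d", 1:500),
                    A = runif(500), M = rnorm(500))
  w <- make_windows(pts, window_config(100, 50))
  ord <- attr(w, "order")
  expect_equal(pts$A[ord], sort(pts$A))
  for (i in seq_along(w)) {
    expect_false(is.unsorted(pts$A[w[[i]]]))
  }
  expect_setequal(unique(unlist(w)), 1:500)
})

test_that("plotting positions telescope for complete samples", {
  a <- 0.3175
  # closed form (i - a) / (n - 2a + 1) for the complete sample
  pp5 <- plotting_positions(5, a = a)
  expect_equal(pp5$p, (1:5 - a) / 5.365, tolerance = 1e-12)
  for (n in c(2, 17, 400, 1000)) {
    pp <- plotting_positions(n, a = a)
    expect_equal(pp$p, (seq_len(n) - a) / (n - 2 * a + 1), tolerance = 1e-12)
    # complete-sample symmetry: p_i + p_{n+1-i} = 1, hence antisymmetric q
    expect_equal(pp$p + rev(pp$p), rep(1, n), tolerance = 1e-12)
    expect_equal(pp$q, -rev(pp$q), tolerance = 1e-9)
  }
})

test_that("subset plotting positions match the brute-force product", {
  expect_equal(plotting_positions(8, omega = 3:6, a = 0.3175)$p,
               brute_force_positions(8, 3:6, 0.3175), tolerance = 1e-14)
  set.seed(51)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    omega <- sort(sample.int(n, sample(2:n, 1)))
    aa <- runif(1, 0, 0.9)
    expect_equal(plotting_positions(n, omega, aa)$p,
                 brute_force_positions(n, omega, aa), tolerance = 1e-14)
  }
  expect_error(plotting_positions(10, integer(0)), "non-empty")
  expect_error(plotting_positions(10, c(2, 11)), "subset")
})

test_that("QQ regression recovers exact linear data and flags degeneracy", {
  cfg <- window_config(window_size = 40, step = 40)
  q <- plotting_positions(40, a = cfg$qq_a)$q
  est <- qq_regression(0.3 + 0.5 * q, cfg)
  expect_equal(est$mu, 0.3, tolerance = 1e-12)
  expect_equal(est$sigma, 0.5, tolerance = 1e-12)
  expect_equal(est$sigma2, 0.25, tolerance = 1e-12)
  expect_equal(est$r_squared, 1, tolerance = 1e-12)
  expect_false(est$degenerate)

  flat <- qq_regression(rep(1.2, 40), cfg)
  expect_true(flat$degenerate)
  expect_equal(flat$sigma, 0)
  expect_equal(flat$mu, 1.2)
})

test_that("QQ regression slope is location-invariant and scale-equivariant", {
  set.seed(61)
  m <- rnorm(400, 0, 0.5)
  base <- qq_regression(m)
  shifted <- qq_regression(m + 3.7)
  expect_equal(shifted$sigma, base$sigma, tolerance = 1e-12)
  expect_equal(shifted$mu, base$mu + 3.7, tolerance = 1e-12)
  scaled <- qq_regression(m * 2.5)
  expect_equal(scaled$sigma, base$sigma * 2.5, tolerance = 1e-12)
  expect_equal(scaled$r_squared, base$r_squared, tolerance = 1e-12)
})

test_that("QQ regression slope is an unbiased scale estimate (Monte Carlo)", {
  set.seed(71)
  sigma_hat <- replicate(200, qq_regression(rnorm(400, 0, 0.5))$sigma)
  # 5 standard errors of the mean over 200 replicates
  tol <- 5 * sd(sigma_hat) / sqrt(200)
  expect_lt(abs(mean(sigma_hat) - 0.5), tol)
})

test_that("variance-function fit handles degenerate and exact cases", {
  # constant variance: theta2 = 0, theta1 = log(v), perfect fit
  est <- data.frame(mean_A = c(10, 15, 20), sigma2 = 0.3, mu = 0,
                    degenerate = FALSE)
  m <- fit_variance_function(est)
  expect_equal(m$theta2, 0, tolerance = 1e-8)
  expect_equal(m$theta1, log(0.3), tolerance = 1e-8)
  expect_equal(m$fit_r_squared, 1)
  # two windows: exact interpolation
  est2 <- data.frame(mean_A = c(10, 20), sigma2 = c(0.5, 0.01), mu = 0,
                     degenerate = FALSE)
  m2 <- fit_variance_function(est2)
  expect_equal(predict(m2, c(10, 20)), c(0.5, 0.01), tolerance = 1e-10)
  expect_equal(m2$fit_r_squared, 1, tolerance = 1e-10)
  expect_error(fit_variance_function(est2[1, ]), "at least 2")
})

test_that("variance-function parameters are recovered from noisy windows", {
  set.seed(81)
  A <- seq(10, 25, length.out = 30)
  truth <- exp(2 - 0.4 * A)
  est <- data.frame(mean_A = A,
                    sigma2 = truth * (1 + rnorm(30, 0, 0.01)),
                    mu = rnorm(30, 0, 0.01), degenerate = FALSE)
  for (w in c("relative", "absolute")) {
    m <- fit_variance_function(est, weighting = w)
    expect_lt(abs(m$theta1 - 2) / 2, 0.05)
    expect_lt(abs(m$theta2 + 0.4) / 0.4, 0.05)
  }
})

test_that("stringent variance dominates and sigma_mu_sq is the mu variance", {
  est <- data.frame(mean_A = c(10, 15, 20), sigma2 = c(0.4, 0.1, 0.02),
                    mu = c(-0.02, 0.01, 0.04), degenerate = FALSE)
  m <- fit_variance_function(est)
  expect_equal(m$sigma_mu_sq, var(c(-0.02, 0.01, 0.04)))
  A <- seq(8, 26, by = 0.5)
  expect_true(all(stringent_sigma2(A, m) >=
                    suppressMessages(predict(m, A))))
  # toy constant model: theta = (0, 0), sigma_mu_sq = 1 -> sigma2 = 2
  toy <- structure(list(theta1 = 0, theta2 = 0, sigma_mu_sq = 1,
                        A_range = c(0, 30)), class = "VarianceModel")
  expect_equal(stringent_sigma2(c(1, 10, 20), toy), rep(2, 3))
})

test_that("rescaled ordered-ratio summary is exact on constructed windows", {
  cfg <- window_config(window_size = 40, step = 40)
  q <- plotting_positions(40, a = cfg$qq_a)$q
  # single window with ordered M exactly sigma * q: means equal q, SDs zero
  set.seed(3)
  pts <- data.frame(protein_id = sprintf("p%02d", 1:40),
                    A = seq(1, 4, length.out = 40),
                    M = sample(0.5 * q))
  model <- structure(list(
    window_estimates = data.frame(window = 1, sigma = 0.5,
                                  degenerate = FALSE)),
    class = "VarianceModel")
  s <- rescaled_qq_summary(pts, model, cfg)
  expect_equal(s$mean, sort(q), tolerance = 1e-12)
  expect_equal(s$sd, rep(0, 40))
  expect_equal(attr(s, "n_windows"), 1L)
})

test_that("windows with identical content give zero SD at every rank", {
  set.seed(91)
  m <- rnorm(60, 0, 0.3)
  pts <- data.frame(protein_id = sprintf("p%03d", 1:120),
                    A = c(seq(1, 2, length.out = 60),
                          seq(3, 4, length.out = 60)),
                    M = c(m, m))
  cfg <- window_config(window_size = 60, step = 60)
  model <- build_error_model(pts, cfg)
  s <- rescaled_qq_summary(pts, model, cfg)
  expect_equal(attr(s, "n_windows"), 2L)
  expect_equal(s$sd, rep(0, 60), tolerance = 1e-12)
})
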