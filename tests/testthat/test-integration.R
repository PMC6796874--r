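test_that("rank statistics combine runs by order statistics and average Z", {
  runs <- list(
    fake_run(c("a", "b", "c"), c(3, 1, 1)),
    fake_run(c("a", "b"), c(2.5, -1)),
    fake_run(c("a", "b", "c"), c(2, 0.5, 1)))
  runs[[1]]$P[1] <- 0.01; runs[[2]]$P[1] <- 0.2; runs[[3]]$P[1] <- 0.5
  out <- rank_statistics(runs)
  a <- out[out$protein_id == "a", ]
  expect_equal(a$k, 3L)
  expect_equal(a$best_P, 0.01)
  expect_equal(a$second_best_P, 0.2)
  expect_equal(a$avg_Z, (3 + 2.5 + 2) / sqrt(3))
  # k = 1: second best absent, avg Z reduces to the single run's Z
  single <- rank_statistics(list(fake_run("x", 1.7)))
  expect_equal(single$k, 1L)
  expect_true(is.na(single$second_best_P))
  expect_equal(single$avg_Z, 1.7)
  # k = 4 with all Z = 1: average Z = 4 / sqrt(4) = 2
  four <- rank_statistics(rep(list(fake_run("y", 1)), 4))
  expect_equal(four$avg_Z, 2)
  expect_error(rank_statistics(list()), "non-empty")
})

test_that("second-best P is never smaller than best P", {
  set.seed(121)
  runs <- lapply(1:3, function(i) {
    ids <- sample(sprintf("P%03d", 1:80), 60)
    fake_run(ids, rnorm(60))
  })
  out <- rank_statistics(runs)
  multi <- out[out$k >= 2, ]
  expect_true(all(multi$second_best_P >= multi$best_P))
  # a single outlying small P moves the best rank but not the second-best
  base <- list(fake_run(c("u", "v"), c(0.1, 0.1)),
               fake_run(c("u", "v"), c(0.1, 8)))
  r <- rank_statistics(base)
  expect_equal(which.min(r$best_P), match("v", r$protein_id))
  expect_equal(r$second_best_P[r$protein_id == "v"],
               r$second_best_P[r$protein_id == "u"])
})

test_that("average-Z P-values are two-tailed standard normal", {
  expect_equal(avg_z_pvalue(0), 1)
  expect_equal(avg_z_pvalue(qnorm(0.975)), 0.05)
  expect_equal(avg_z_pvalue(-qnorm(0.975)), 0.05)
  expect_error(avg_z_pvalue(Inf), "finite")
})

test_that("average Z over independent null runs is standard normal", {
  set.seed(131)
  n <- 5000
  runs <- lapply(1:3, function(i) fake_run(sprintf("P%04d", 1:n), rnorm(n)))
  out <- rank_statistics(runs)
  expect_lt(abs(mean(out$avg_Z)), 0.05)
  expect_gt(sd(out$avg_Z), 0.95)
  expect_lt(sd(out$avg_Z), 1.05)
  expect_lt(abs(mean(out$avg_Z_P < 0.05) - 0.05), 0.01)
})

test_that("resampled null FDR is near 1 on pure-null runs", {
  set.seed(141)
  n <- 2000
  runs <- lapply(1:3, function(i) fake_run(sprintf("P%04d", 1:n), rnorm(n)))
  for (st in c("second_best_p", "avg_z")) {
    f <- permutation_fdr(runs, st, n_permutations = 100, seed = 17)
    bulk <- f$n_discoveries >= 100
    expect_gt(min(f$fdr[bulk]), 0.7)
    expect_gt(median(f$fdr, na.rm = TRUE), 0.85)
  }
})

test_that("FDR tracks the realized false-discovery proportion on spiked runs", {
  set.seed(151)
  n <- 1500
  dep <- seq_len(n) <= 150
  runs <- lapply(1:3, function(i) {
    fake_run(sprintf("P%04d", 1:n), rnorm(n) + ifelse(dep, 4, 0))
  })
  f <- permutation_fdr(runs, "second_best_p", n_permutations = 200, seed = 23)
  thr <- sort(f$statistic[dep])[round(0.5 * sum(dep))]
  declared <- f$statistic <= thr
  fdp <- mean(!dep[declared])
  est <- f$fdr[f$statistic == thr][1]
  expect_lt(abs(est - fdp), 0.1)
  # doubling the rounds moves estimates by less than Monte-Carlo noise
  f2 <- permutation_fdr(runs, "second_best_p", n_permutations = 400, seed = 24)
  expect_lt(max(abs(f2$fdr - f$fdr), na.rm = TRUE), 0.1)
})

test_that("permutation FDR validates its inputs", {
  runs <- lapply(1:2, function(i) fake_run(c("a", "b", "c"), rnorm(3)))
  expect_error(permutation_fdr(runs[1], seed = 1), "at least 2 runs")
  expect_error(permutation_fdr(runs, n_permutations = 5, seed = 1),
               "at least 10")
  expect_error(permutation_fdr(runs, n_permutations = 50), "seed")
})

test_that("consistency score counts matching directions in the overlap", {
  ref <- c(a = 1, b = -1, c = -1, d = 1, e = 1)
  expect_equal(as.numeric(consistency_score(c(a = 1, b = -1), ref)), 1)
  sc <- consistency_score(c(a = 1, b = -1, c = 1, d = 1), ref)
  expect_equal(as.numeric(sc), 0.75)
  expect_equal(attr(sc, "n_inconsistent"), 1L)
  # proteins absent from the reference are excluded from both counts
  expect_equal(as.numeric(consistency_score(c(a = 1, zz = -1), ref)), 1)
  expect_error(consistency_score(c(q = 1), ref), "overlap")
  expect_error(consistency_score(c(a = 2), ref), "\\+1/-1")
})

test_that("reference directions drop ratios inside the threshold band", {
  r <- c(g1 = 0.5, g2 = -0.3, g3 = 0.1)
  expect_equal(filter_reference_directions(r, 0.2), c(g1 = 1, g2 = -1))
  expect_length(filter_reference_directions(c(x = 0.1, y = -0.15), 0.2), 0)
  expect_error(filter_reference_directions(r, 0), "positive")
})

test_that("map_integrate attaches FDR columns for multi-run input", {
  set.seed(161)
  n <- 300
  runs <- lapply(1:3, function(i) fake_run(sprintf("P%03d", 1:n), rnorm(n)))
  out <- map_integrate(runs, n_permutations = 50, seed = 3)
  expect_s3_class(out, "IntegrationResult")
  expect_true(all(c("fdr_second_best", "fdr_avg_z") %in% names(out)))
  expect_true(all(out$avg_Z_P_adj >= out$avg_Z_P))
})
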