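#' Configuration for the synthetic proteome generator
#'
#' Describes a simulated two-condition isobaric-labeling experiment with
#' the statistical structure the error model assumes: mean log2 intensities
#' spanning a wide dynamic range, null log2 ratios drawn from
#' `N(0, exp(theta1 + theta2 * A))`, and an optional spiked fraction of
#' differential proteins with a fixed log2 effect split symmetrically
#' between up- and down-regulation (so spiking does not bias the global
#' normalization).
#'
#' Defaults describe the reference simulation used throughout the package's
#' validation: 5000 proteins, A uniform on [10, 25], theta = (2.0, -0.4)
#' (null SD from about 0.37 at the low-intensity end down to 0.018 at the
#' high end), 10% differential proteins with a 1.5 log2-unit shift, three
#' runs.
#'
#' @param n_proteins Number of proteins; default 5000.
#' @param a_range Range of the uniform distribution of mean log2
#'   intensities; default `c(10, 25)`.
#' @param theta1,theta2 True variance-function parameters; default 2.0 and
#'   -0.4.
#' @param dep_fraction Fraction of differential proteins in `[0, 1)`;
#'   default 0.1.
#' @param dep_effect Log2 shift magnitude of the spiked differential
#'   proteins; default 1.5.
#' @param n_runs Number of replicate runs for [simulate_multi_run()];
#'   default 3.
#' @param dropout Per-run probability that a protein goes undetected, in
#'   `[0, 1)`; default 0 (identical protein universe in every run).
#' @param technical_replicate If `TRUE`, the two profiles are technical
#'   replicates of the same sample: `dep_fraction` is forced to 0 and all
#'   observed ratios are error.
#' @param seed Mandatory integer RNG seed.
#' @return A validated `SimulationConfig` list.
#' @export
simulation_config <- function(n_proteins = 5000, a_range = c(10, 25),
                              theta1 = 2.0, theta2 = -0.4,
                              dep_fraction = 0.1, dep_effect = 1.5,
                              n_runs = 3, dropout = 0,
                              technical_replicate = FALSE, seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("'seed' is mandatory for reproducible simulation")
  }
  if (n_proteins < 1) stop("'n_proteins' must be positive")
  if (length(a_range) != 2 || a_range[1] >= a_range[2]) {
    stop("'a_range' must be an increasing pair")
  }
  if (!(dep_fraction >= 0 && dep_fraction < 1)) {
    stop("'dep_fraction' must be in [0, 1)")
  }
  if (dep_fraction > 0 && dep_effect <= 0) {
    stop("'dep_effect' must be positive when proteins are spiked")
  }
  if (!(dropout >= 0 && dropout < 1)) stop("'dropout' must be in [0, 1)")
  if (technical_replicate) dep_fraction <- 0
  s2 <- exp(theta1 + theta2 * a_range)
  if (any(!is.finite(s2)) || any(s2 <= 0)) {
    stop("variance function must be positive and finite over 'a_range'")
  }
  structure(list(n_proteins = as.integer(n_proteins), a_range = a_range,
                 theta1 = theta1, theta2 = theta2,
                 dep_fraction = dep_fraction, dep_effect = dep_effect,
                 n_runs = as.integer(n_runs), dropout = dropout,
                 technical_replicate = technical_replicate,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

# shared protein universe: ids, A values, differential labels and signed
# effects; all randomness after set.seed() by the caller
draw_universe <- function(cfg) {
  n <- cfg$n_proteins
  ids <- sprintf("P%05d", seq_len(n))
  A <- stats::runif(n, cfg$a_range[1], cfg$a_range[2])
  sigma2 <- exp(cfg$theta1 + cfg$theta2 * A)
  effect <- numeric(n)
  n_dep <- round(cfg$dep_fraction * n)
  if (n_dep > 0) {
    dep_idx <- sample.int(n, n_dep)
    dirs <- rep(c(1, -1), length.out = n_dep)[sample.int(n_dep)]
    effect[dep_idx] <- dirs * cfg$dep_effect
  }
  list(ids = ids, A = A, sigma2 = sigma2, effect = effect)
}

draw_run <- function(universe, cfg, run_id) {
  M <- stats::rnorm(cfg$n_proteins, mean = universe$effect,
                    sd = sqrt(universe$sigma2))
  pair <- condition_pair(universe$ids,
                         2^(universe$A + M / 2),
                         2^(universe$A - M / 2),
                         conditions = if (cfg$technical_replicate) {
                           c("replicate_1", "replicate_2")
                         } else c("condition_1", "condition_2"),
                         run_id = run_id)
  list(pair = pair, M = M)
}

#' Simulate one two-condition profile pair
#'
#' Per protein: draw A, draw the error component of M from
#' `N(0, exp(theta1 + theta2 * A))`, add the signed effect for spiked
#' differential proteins, and back-solve raw-scale intensities
#' `S1 = 2^(A + M/2)`, `S2 = 2^(A - M/2)` so that the MA transform of the
#' pair reproduces the drawn (A, M) exactly. The same seed always yields a
#' bit-identical result.
#'
#' @param cfg A `SimulationConfig`.
#' @return List with `pair` (a `ConditionPair`) and `truth` (data frame
#'   with `protein_id`, `A`, `M`, `sigma2_true`, `effect`, `is_dep`).
#' @export
simulate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  universe <- draw_universe(cfg)
  run <- draw_run(universe, cfg, run_id = "sim_run_1")
  list(pair = run$pair,
       truth = data.frame(protein_id = universe$ids,
                          A = universe$A, M = run$M,
                          sigma2_true = universe$sigma2,
                          effect = universe$effect,
                          is_dep = universe$effect != 0,
                          stringsAsFactors = FALSE))
}

#' Simulate replicate runs sharing the same differential proteins
#'
#' All runs share one protein universe, A values, and differential labels
#' with their signed effects; the error component of M is drawn
#' independently per run. Optionally each protein drops out of each run
#' independently with probability `dropout`, emulating partial detection
#' across MS runs.
#'
#' @param cfg A `SimulationConfig` with `n_runs >= 2`.
#' @return List with `runs` (list of `ConditionPair`s) and `truth` (shared
#'   truth table with one logical `detected_run<t>` column per run).
#' @export
simulate_multi_run <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (cfg$n_runs < 2) stop("'n_runs' must be at least 2")
  set.seed(cfg$seed)
  universe <- draw_universe(cfg)
  truth <- data.frame(protein_id = universe$ids,
                      A = universe$A,
                      sigma2_true = universe$sigma2,
                      effect = universe$effect,
                      is_dep = universe$effect != 0,
                      stringsAsFactors = FALSE)
  runs <- vector("list", cfg$n_runs)
  for (t in seq_len(cfg$n_runs)) {
    run <- draw_run(universe, cfg, run_id = sprintf("sim_run_%d", t))
    detected <- if (cfg$dropout > 0) {
      stats::runif(cfg$n_proteins) >= cfg$dropout
    } else rep(TRUE, cfg$n_proteins)
    pair <- run$pair[detected, , drop = FALSE]
    runs[[t]] <- condition_pair(pair$protein_id, pair$intensity_a,
                                pair$intensity_b,
                                conditions = attr(run$pair, "conditions"),
                                run_id = attr(run$pair, "run_id"))
    truth[[sprintf("detected_run%d", t)]] <- detected
  }
  list(runs = runs, truth = truth)
}

#' Split a condition pair into a four-channel intensity table
#'
#' Emulates technical-replicate labeling channels: each condition's
#' intensity is split between its two reporter channels with a random
#' proportion drawn uniformly from [0.4, 0.6], so the channel sums
#' reconstruct the condition intensities exactly and
#' [combine_channels()] inverts this operation.
#'
#' @param pair A `ConditionPair`.
#' @param channels Four channel column names, the first two for condition
#'   a; default iTRAQ-style `it114`, `it115`, `it116`, `it117`.
#' @return A `ProteinProfile` data frame.
#' @export
as_profile_table <- function(pair, channels = c("it114", "it115",
                                                "it116", "it117")) {
  stopifnot(inherits(pair, "ConditionPair"), length(channels) == 4)
  n <- nrow(pair)
  fa <- stats::runif(n, 0.4, 0.6)
  fb <- stats::runif(n, 0.4, 0.6)
  out <- data.frame(protein_id = pair$protein_id, stringsAsFactors = FALSE)
  out[[channels[1]]] <- pair$intensity_a * fa
  out[[channels[2]]] <- pair$intensity_a * (1 - fa)
  out[[channels[3]]] <- pair$intensity_b * fb
  out[[channels[4]]] <- pair$intensity_b * (1 - fb)
  structure(out, run_id = attr(pair, "run_id"), channels = channels,
            class = c("ProteinProfile", "data.frame"))
}

#' Write a profile table as TSV
#'
#' Emits the same dialect [load_profile_table()] reads (header row,
#' tab-separated, full numeric precision).
#'
#' @param profile A `ProteinProfile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_table <- function(profile, path) {
  stopifnot(inherits(profile, "ProteinProfile"))
  out <- as.data.frame(profile)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- "NA"
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
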