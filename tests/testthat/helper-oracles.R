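# Independent oracles and small fixture builders used across the suite.

# Michael-Schucany plotting position, evaluated term by term straight from
# the product definition (no telescoping, no vectorized cumprod).
brute_force_positions <- function(n, omega, a) {
  vapply(omega, function(i) {
    prod <- 1
    for (j in omega) {
      if (j >= i) prod <- prod * (j - a) / (j - a + 1)
    }
    (n - a + 1) / (n - 2 * a + 1) * prod
  }, numeric(1))
}

# Benjamini-Hochberg step-up from the definition: adjusted p for the i-th
# smallest p is min over j >= i of n * p_(j) / j, capped at 1.
brute_force_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in i:n) {
      best <- min(best, n * p[o[j]] / j)
    }
    adj[o[i]] <- min(1, best)
  }
  adj
}

# small hand-checkable condition pair
toy_pair <- function(a = c(10, 12, 11, 9, 100, 13),
                     b = c(20, 24, 22, 18, 28, 26)) {
  condition_pair(sprintf("prot%02d", seq_along(a)), a, b)
}

write_tsv_lines <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

# per-run results table shaped like a ComparisonResult, from raw Z values
fake_run <- function(ids, z) {
  data.frame(protein_id = ids, Z = z,
             P = pmax(2 * pnorm(abs(z), lower.tail = FALSE),
                      .Machine$double.xmin),
             stringsAsFactors = FALSE)
}
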