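# Independent brute-force oracles used to cross-check the implementation.

# Pairwise double-loop A statistic (the definition, enumerated).
a_test_oracle <- function(x, y) {
  gt <- 0
  eq <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) gt <- gt + 1
    else if (xi == yj) eq <- eq + 1
  }
  (gt + 0.5 * eq) / (length(x) * length(y))
}

# Wrapped distance on the periodic-x / plain-y topology, in R.
wdist_oracle <- function(p, q, width) {
  dx <- abs(p[1] - q[1])
  dx <- min(dx, width - dx)
  sqrt(dx^2 + (p[2] - q[2])^2)
}

# Single-linkage components by transitive closure over the pairwise
# distance graph (O(n^3), fine for <= 200 cells).
single_linkage_oracle <- function(x, y, width, linking) {
  n <- length(x)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- wdist_oracle(c(x[i], y[i]), c(x[j], y[j]), width) <= linking
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  lab <- integer(n)
  nextlab <- 0L
  for (i in seq_len(n)) {
    if (lab[i] == 0L) {
      nextlab <- nextlab + 1L
      lab[adj[i, ]] <- nextlab
    }
  }
  lab
}

# A deliberately minimal environment for geometry-level tests.
bare_env <- function(width = 5000, height = 1000) {
  list(width = width, height = height)
}

# Small configs used throughout the suite.
test_cfg <- function(...) sim_config("test", ...)
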