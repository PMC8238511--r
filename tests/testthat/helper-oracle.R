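# Independent oracles and small fixtures shared across tests.

# Exhaustive path enumeration: occupancy at cycle t as a sum over all state
# paths of length t of the product of one-step transition probabilities.
# Deliberately brute force and independent of the matrix-product engine.
enumerate_paths <- function(initial, matrices) {
  n <- length(initial)
  T <- length(matrices)
  occ <- matrix(0, T + 1, n)
  occ[1, ] <- initial
  for (t in seq_len(T)) {
    paths <- as.matrix(expand.grid(rep(list(seq_len(n)), t + 1)))
    for (k in seq_len(nrow(paths))) {
      pr <- initial[paths[k, 1]]
      for (s in seq_len(t)) {
        pr <- pr * matrices[[s]][paths[k, s], paths[k, s + 1]]
        if (pr == 0) break
      }
      occ[t + 1, paths[k, t + 1]] <- occ[t + 1, paths[k, t + 1]] + pr
    }
  }
  occ
}

# random valid baseline row (five outcome probabilities summing to <= 1)
random_baseline_row <- function() {
  x <- runif(6)
  x <- x / sum(x)
  c(employment = x[1], unemployment = x[2], lt_sickness = x[3],
    early_retirement = x[4], disability = x[5])
}
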