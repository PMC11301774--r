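# Shared independent oracles for the test suite.

# Exhaustive pairwise-merge grouping: connected components of the graph
# linking any two masses within the precision (union-find). Reference for
# the sorted chained-greedy merge.
oracle_groups <- function(masses, precision) {
  n <- length(masses)
  if (!n) return(0L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(masses[i] - masses[j]) <= precision + 1e-9) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}
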