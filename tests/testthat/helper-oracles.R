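# Independent oracles used against the implementation.

# Brute-force over-representation p-value: enumerate every n-subset of a
# universe of size N whose first K elements are "in the set" and count draws
# with overlap >= k.  Returns the exact rational as numerator/denominator.
ora_oracle <- function(k, K, n, N) {
  if (n == 0) return(list(num = if (k == 0) 1 else 0, den = 1, p = as.numeric(k == 0)))
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)  # elements 1..K are the gene set
  list(num = sum(overlap >= k), den = ncol(draws),
       p = sum(overlap >= k) / ncol(draws))
}

# Hand step-up Benjamini-Hochberg, independent of stats::p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Direct two-body force simulation for the Fruchterman-Reingold equilibrium:
# two connected nodes settle where repulsion k^2/d equals attraction d^2/k,
# i.e. at distance k.
fr_two_node_equilibrium <- function(width, height, n = 2) {
  sqrt(width * height / n)
}
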