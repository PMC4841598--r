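# Independent oracles kept deliberately separate from the implementation.

# Direct (non-log) summation of the two-library Poisson exact test.  For a
# fixed x and library ratio, returns p-values for all y in 0..y_max at once
# via the cumulative sum of P(i|x).
ac_oracle_row <- function(x, y_max, N1, N2) {
  r <- N2 / N1
  i <- 0:y_max
  P <- exp(i * log(r) + lgamma(x + i + 1) - lgamma(x + 1) - lgamma(i + 1) -
             (x + i + 1) * log(1 + r))
  C <- cumsum(P)
  p <- ifelse(C <= 0.5, 2 * C, 2 * (1 - C))
  pmin(p, 1)
}

ac_oracle <- function(x, y, N1, N2) ac_oracle_row(x, y, N1, N2)[y + 1]

# hand-applied Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# toy count_matrix fixture used across tests
toy_count_matrix <- function() {
  counts <- matrix(c(10L, 0L, 100L, 50L,
                     20L, 5L, 80L, 55L),
                   nrow = 4,
                   dimnames = list(c("g1", "g2", "g3", "g4"),
                                   c("WT170", "MT170")))
  count_matrix(counts,
               library_sizes = c(WT170 = 1e6, MT170 = 1e6),
               gene_lengths = c(g1 = 1000, g2 = 500, g3 = 2000, g4 = 1500))
}
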