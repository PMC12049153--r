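# Independent brute-force oracles used by both the unit tests and the
# acceptance tests. Written directly from the definitions, not from the
# package implementations.

# capped rank-sum signature score per cell
ucell_oracle <- function(expr, signatures, rank_cap = 1500) {
  out <- matrix(NA_real_, nrow(expr), length(signatures),
                dimnames = list(rownames(expr), names(signatures)))
  for (i in seq_len(nrow(expr))) {
    r <- pmin(rank(-expr[i, ], ties.method = "average"), rank_cap + 1)
    for (j in seq_along(signatures)) {
      s <- signatures[[j]]
      rs <- r[s]
      rs[is.na(rs)] <- rank_cap + 1
      n <- length(s)
      u <- sum(rs) - n * (n + 1) / 2
      out[i, j] <- max(0, 1 - u / (n * rank_cap))
    }
  }
  out
}

# 1-df log-rank chi-square from the observed-minus-expected tables
logrank_oracle <- function(times, events, g1) {
  o1 <- e1 <- v1 <- 0
  for (tt in sort(unique(times[events]))) {
    at <- times >= tt
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(times == tt & events)
    d1 <- sum(times == tt & events & g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v1 <- v1 + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1) ^ 2 / v1
}

# exact two-sided Wilcoxon rank-sum p-value by full enumeration of the
# choose(n1 + n2, n1) equally likely group assignments (untied data)
wilcoxon_exact_oracle <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(r), n1)
  us <- colSums(matrix(r[combs], n1)) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}
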