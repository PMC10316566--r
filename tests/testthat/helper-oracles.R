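# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# Literal step-up BH: adj_(i) = min_{j >= i}(p_(j) * m / j), capped at 1.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Exact two-sided rank-sum p-value by full enumeration of group
# assignments (no ties assumed; feasible for n <= 12).
exact_wilcoxon_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  u_all <- apply(combos, 2, function(j) sum(r[j]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (n - n1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# Spearman as rank-then-Pearson.
rank_pearson <- function(x, y) stats::cor(rank(x), rank(y))

# Poisson two-group closed form with offsets (size factors): the MLE rate
# of a group is S_g / sum(sf_g); Wald coefficient and SE follow.
poisson_two_group <- function(counts, sf, j1, j2) {
  s1 <- sum(counts[j1]); s2 <- sum(counts[j2])
  beta <- log(s2 / sum(sf[j2])) - log(s1 / sum(sf[j1]))
  list(beta = beta, se = sqrt(1 / s1 + 1 / s2))
}
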