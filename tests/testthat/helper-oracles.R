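# Independent oracles: brute-force / closed-form implementations used to
# check the package's statistics. These never call the functions they
# verify.

# Exact two-sided Mann-Whitney p by enumeration of all rank assignments.
mw_exact_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * n2 / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Normal-approximation Mann-Whitney p from the textbook midrank formula
# with tie correction and 0.5 continuity correction.
mw_normal_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- (n1 * n2 / 12) * (n + 1 - tie_term)
  z <- (u - n1 * n2 / 2)
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
  2 * min(stats::pnorm(z), 1 - stats::pnorm(z), 0.5)
}

# Two-tailed Fisher exact p by hypergeometric probability-mass summation.
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson chi-square by the direct formula.
chisq_oracle <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# BH step-up adjusted p-values by direct application of the formula.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  adj[o] <- rev(cummin(rev(pmin(sorted, 1))))
  adj
}

# Exhaustive-search k-medoids optimum: minimal total distance to the best
# medoid set, over all size-k subsets.
pam_brute_force <- function(d, k) {
  n <- nrow(d)
  best <- Inf
  combos <- utils::combn(n, k)
  for (c_i in seq_len(ncol(combos))) {
    med <- combos[, c_i]
    cost <- sum(apply(d[, med, drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}
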