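# Brute-force oracles, kept deliberately independent of the implementations
# they check.

# two-sided Fisher p by direct enumeration with binomial coefficients
# (probability-mass rule)
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - r2):min(r1, c1)
  pr <- vapply(support, function(k) {
    choose(r1, k) * choose(r2, c1 - k) / choose(n, c1)
  }, numeric(1))
  p_obs <- pr[match(a, support)]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumeration of all subsets of pooled ranks
mw_oracle <- function(x, y) {
  n <- length(x) + length(y); nx <- length(x)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * (n - nx) / 2
  splits <- combn(n, nx)
  us <- apply(splits, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# exact two-sided signed-rank p by enumeration of all 2^n sign assignments
signrank_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9)
}

# Benjamini-Hochberg step-up by the printed definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# two-sample Welch t from the textbook formulas; returns the two-sided p
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  t_stat <- (mean(x) - mean(y)) / sqrt(vx / nx + vy / ny)
  df <- (vx / nx + vy / ny)^2 /
    ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * pt(-abs(t_stat), df)
}

# tie-corrected Kruskal-Wallis H recomputed independently via kruskal.test
kw_stat_oracle <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  unname(kruskal.test(x, g)$statistic)
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2)); sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}
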