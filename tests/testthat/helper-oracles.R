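# Independent brute-force oracles used to cross-check the package's
# statistics. These deliberately use naive enumeration / closed forms and
# never call the implementation under test.

# Benjamini-Hochberg step-up by direct definition:
# q_(i) = min_{j >= i} min(1, m * p_(j) / j), in the original order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, m * p[o] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Pearson chi-square by direct double loop over cells.
chisq_oracle <- function(tab) {
  rs <- rowSums(tab)
  cs <- colSums(tab)
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- rs[i] * cs[j] / n
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  stat
}

# Two-sample KS statistic by evaluating both ECDFs at every data value.
ks_oracle <- function(x, y) {
  grid <- c(x, y)
  max(vapply(grid, function(g) abs(mean(x <= g) - mean(y <= g)), numeric(1)))
}

# One-sided (enrichment) Fisher p by enumerating hypergeometric tables
# with overlap >= k.
fisher_oracle <- function(k, n_genes, n_set, background) {
  kk <- k:min(n_genes, n_set)
  sum(exp(lchoose(n_set, kk) + lchoose(background - n_set, n_genes - kk) -
            lchoose(background, n_genes)))
}

# Closed-form OLS for simple linear regression.
ols_oracle <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Rigid 3D rotation matrix from an axis (unit vector) and angle.
rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c1 <- cos(angle)
  s1 <- sin(angle)
  ux <- axis[1]; uy <- axis[2]; uz <- axis[3]
  matrix(c(
    c1 + ux^2 * (1 - c1), ux * uy * (1 - c1) - uz * s1,
    ux * uz * (1 - c1) + uy * s1,
    uy * ux * (1 - c1) + uz * s1, c1 + uy^2 * (1 - c1),
    uy * uz * (1 - c1) - ux * s1,
    uz * ux * (1 - c1) - uy * s1, uz * uy * (1 - c1) + ux * s1,
    c1 + uz^2 * (1 - c1)), 3, 3, byrow = TRUE)
}
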