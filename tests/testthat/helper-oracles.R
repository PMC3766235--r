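# Independent brute-force oracles. Each is deliberately coded from the
# definition, not by calling the package's internals.

# quantile rule fixed to type 7 everywhere
oracle_quartiles <- function(x) {
  stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
}

oracle_agreement <- function(egfr, sgfr, tols = c(0.15, 0.30, 0.50)) {
  d <- egfr - sgfr
  qd <- oracle_quartiles(d)
  qa <- oracle_quartiles(abs(d))
  out <- list(n = length(d),
              median_diff = qd[2], diff_q1 = qd[1], diff_q3 = qd[3],
              median_abs_diff = qa[2], abs_diff_q1 = qa[1], abs_diff_q3 = qa[3])
  for (tol in tols) {
    cnt <- 0L
    for (i in seq_along(d)) if (abs(egfr[i] - sgfr[i]) / sgfr[i] < tol) cnt <- cnt + 1L
    out[[sprintf("p%d_count", round(100 * tol))]] <- cnt
    out[[sprintf("p%d_pct", round(100 * tol))]] <- 100 * cnt / length(d)
  }
  out
}

oracle_bland_altman <- function(egfr, sgfr) {
  d <- egfr - sgfr
  m <- sum(d) / length(d)
  s <- sqrt(sum((d - m)^2) / (length(d) - 1))
  list(mean_diff = m, sd_diff = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s, loa_width = 3.92 * s)
}

# dense minimum-norm least squares on the bias-augmented Gaussian design,
# via MASS::ginv (independent pseudo-inverse route)
oracle_rbf_theta <- function(x, y, spread) {
  b <- 0.8326 / spread
  A <- cbind(exp(-(b * abs(outer(x, x, "-")))^2), 1)
  drop(MASS::ginv(A) %*% y)
}

oracle_rbf_predict <- function(x_train, theta, spread, x_new) {
  b <- 0.8326 / spread
  P <- cbind(exp(-(b * abs(outer(x_new, x_train, "-")))^2), 1)
  drop(P %*% theta)
}

# exact Wilcoxon signed-rank two-sided p by enumerating all sign patterns
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  w_all <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(mask))[1:n]
    w_all[mask + 1] <- sum(r[signs == 1])
  }
  lo <- mean(w_all <= w_obs + 1e-12)
  hi <- mean(w_all >= w_obs - 1e-12)
  min(1, 2 * min(lo, hi))
}

# exact Mann-Whitney two-sided p by enumerating group assignments
oracle_mwu_exact <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  N <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(N, nx)
  u_all <- numeric(ncol(idx))
  for (j in seq_len(ncol(idx))) {
    u_all[j] <- sum(r[idx[, j]]) - nx * (nx + 1) / 2
  }
  min(1, 2 * min(mean(u_all <= u_obs + 1e-12), mean(u_all >= u_obs - 1e-12)))
}

oracle_kw_H <- function(groups) {
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- rank(pooled)
  sizes <- lengths(groups)
  g <- rep(seq_along(groups), sizes)
  H <- 12 / (N * (N + 1)) * sum(tapply(r, g, sum)^2 / sizes) - 3 * (N + 1)
  ties <- table(pooled)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# random separated RBF training set: inter-point gaps >= 0.5 * spread, the
# regime where the exact design is numerically full-rank
random_separated_set <- function(n, spread) {
  gaps <- stats::runif(n - 1, 0.5, 1.5) * spread
  x <- 0.3 + c(0, cumsum(gaps))
  list(x = x, y = stats::runif(n, 5, 120))
}
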