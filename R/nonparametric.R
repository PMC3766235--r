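#' @title Nonparametric test battery for method-comparison studies
#' @description Exact (small-sample) and asymptotic versions of the Wilcoxon
#'   signed-rank, Mann-Whitney U, Kruskal-Wallis, McNemar and Pearson
#'   chi-square tests, plus Bonferroni adjustment. Exact p-values are
#'   computed by complete enumeration; asymptotic ones use the usual normal /
#'   chi-square references with tie corrections and (following common
#'   statistical-package practice) no continuity correction for the rank
#'   tests. Degenerate inputs (no information) return a flagged result with
#'   p = 1 instead of raising, so pipelines never fall over on a constant
#'   stage group.
#' @name nonparametric-tests
NULL

test_result <- function(statistic, p_value, method, exact, degenerate = FALSE) {
  structure(
    list(statistic = unname(statistic), p_value = min(max(p_value, 0), 1),
         method = method, exact = exact, degenerate = degenerate),
    class = "gfr_test_result"
  )
}

#' @export
print.gfr_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s%s\n", x$method, x$statistic,
              x$p_value, if (x$exact) " (exact)" else " (asymptotic)",
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# two-sided p from a discrete null distribution given as (values, probabilities)
two_sided_from_dist <- function(values, probs, observed) {
  lo <- sum(probs[values <= observed + 1e-12])
  hi <- sum(probs[values >= observed - 1e-12])
  min(1, 2 * min(lo, hi))
}

#' Wilcoxon signed-rank test
#'
#' Two-sided one-sample signed-rank test on a vector of paired differences.
#' Zero differences are dropped. For n <= `exact_max` (default 12) after
#' dropping zeros the null distribution of the positive-rank sum W+ is built
#' by enumerating all 2^n sign patterns (ties handled exactly through
#' midranks); otherwise the normal approximation with tie correction is used.
#'
#' @param d Numeric vector of paired differences.
#' @param exact_max Largest n for which the exact enumeration is used.
#' @return A `gfr_test_result` with `statistic` = W+ (sum of ranks of
#'   positive differences). All-zero input gives a degenerate result with
#'   statistic 0 and p = 1.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3))
#' @export
wilcoxon_signed_rank <- function(d, exact_max = 12) {
  if (length(d) < 1L || anyNA(d)) stopf("`d` must be non-empty and non-missing")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(test_result(0, 1, "wilcoxon_signed_rank", exact = TRUE, degenerate = TRUE))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- drop(signs %*% r)
    p <- two_sided_from_dist(w_all, rep(1 / nrow(signs), nrow(signs)), w_pos)
    test_result(w_pos, p, "wilcoxon_signed_rank", exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sigma2 <= 0) {
      return(test_result(w_pos, 1, "wilcoxon_signed_rank", exact = FALSE, degenerate = TRUE))
    }
    z <- (w_pos - mu) / sqrt(sigma2)
    test_result(w_pos, 2 * stats::pnorm(-abs(z)), "wilcoxon_signed_rank", exact = FALSE)
  }
}

#' Mann-Whitney U test
#'
#' Two-sided two-sample rank test. The statistic is
#' \eqn{U_x = \#\{(i,j): x_i > y_j\} + \tfrac12\#\{x_i = y_j\}}.
#' When `length(x) + length(y) <= exact_max` (default 12) and there are no
#' ties, the exact null distribution is built by enumerating all group
#' assignments; otherwise the normal approximation with tie correction.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param exact_max Total-size limit for exact enumeration.
#' @return A `gfr_test_result`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))
#' @export
mann_whitney_u <- function(x, y, exact_max = 12) {
  if (length(x) < 1L || length(y) < 1L || anyNA(c(x, y))) {
    stopf("both groups must be non-empty and non-missing")
  }
  nx <- length(x); ny <- length(y); N <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  u_x <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  if (N <= exact_max && !has_ties) {
    idx <- utils::combn(N, nx)
    u_all <- apply(idx, 2, function(i) sum(r[i]) - nx * (nx + 1) / 2)
    p <- two_sided_from_dist(u_all, rep(1 / ncol(idx), ncol(idx)), u_x)
    test_result(u_x, p, "mann_whitney_u", exact = TRUE)
  } else {
    mu <- nx * ny / 2
    ties <- table(pooled)
    sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      return(test_result(u_x, 1, "mann_whitney_u", exact = FALSE, degenerate = TRUE))
    }
    z <- (u_x - mu) / sqrt(sigma2)
    test_result(u_x, 2 * stats::pnorm(-abs(z)), "mann_whitney_u", exact = FALSE)
  }
}

#' Kruskal-Wallis rank test across groups
#'
#' H statistic with tie correction, referred to a chi-square distribution
#' with k - 1 degrees of freedom. Use [kruskal_wallis_posthoc()] for the
#' Bonferroni-adjusted pairwise Mann-Whitney follow-up.
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return A `gfr_test_result` with `statistic` = tie-corrected H. If all
#'   pooled values are identical the result is degenerate (H = 0, p = 1).
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stopf("need a list of at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stopf("all groups must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  if (anyNA(pooled)) stopf("groups must be non-missing")
  N <- length(pooled)
  r <- rank(pooled)
  g <- rep(seq_along(groups), sizes)
  Rj <- tapply(r, g, sum)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / sizes) - 3 * (N + 1)
  ties <- table(pooled)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C <= 0) {
    return(test_result(0, 1, "kruskal_wallis", exact = FALSE, degenerate = TRUE))
  }
  H <- H / C
  test_result(H, stats::pchisq(H, df = length(groups) - 1, lower.tail = FALSE),
              "kruskal_wallis", exact = FALSE)
}

#' @rdname kruskal_wallis
#' @param alpha Family-wise level for the pairwise follow-up (default 0.05).
#' @return `kruskal_wallis_posthoc`: list with the omnibus `test`, the
#'   Bonferroni-`adjusted_alpha`, and a data frame `pairwise` of group pairs,
#'   U statistics, p-values and significance flags at the adjusted level.
#' @export
kruskal_wallis_posthoc <- function(groups, alpha = 0.05) {
  omnibus <- kruskal_wallis(groups)
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  adj <- bonferroni_adjust(alpha, ncol(pairs))
  pw <- apply(pairs, 2, function(ij) {
    res <- mann_whitney_u(groups[[ij[1]]], groups[[ij[2]]])
    c(group1 = ij[1], group2 = ij[2], U = res$statistic, p_value = res$p_value)
  })
  pw <- as.data.frame(t(pw))
  pw$significant <- pw$p_value < adj
  list(test = omnibus, adjusted_alpha = adj, pairwise = pw)
}

#' McNemar test on discordant pair counts
#'
#' Paired test of marginal homogeneity for two classifiers scored on the
#' same subjects, driven only by the discordant counts: `b` subjects
#' positive under the first classifier only, `c` under the second only.
#' Exact two-sided binomial p-value `2 * P(X <= min(b, c))`, X ~ Bin(b + c,
#' 1/2), capped at 1, when `b + c <= exact_max` (default 25); otherwise the
#' continuity-corrected chi-square `(|b - c| - 1)^2 / (b + c)` with 1 df.
#'
#' @param b,c Non-negative integer discordant counts.
#' @param exact_max Largest b + c for the exact binomial version.
#' @return A `gfr_test_result`; `b = c = 0` is degenerate with p = 1.
#' @examples
#' mcnemar_test(b = 1, c = 3)
#' @export
mcnemar_test <- function(b, c, exact_max = 25) {
  if (length(b) != 1L || length(c) != 1L || is.na(b) || is.na(c) ||
      b < 0 || c < 0 || b != round(b) || c != round(c)) {
    stopf("`b` and `c` must be single non-negative integers")
  }
  n <- b + c
  if (n == 0) {
    return(test_result(0, 1, "mcnemar", exact = TRUE, degenerate = TRUE))
  }
  if (n <= exact_max) {
    p <- min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
    test_result(min(b, c), p, "mcnemar", exact = TRUE)
  } else {
    stat <- (abs(b - c) - 1)^2 / n
    test_result(stat, stats::pchisq(stat, df = 1, lower.tail = FALSE),
                "mcnemar", exact = FALSE)
  }
}

#' Pearson chi-square test on an r x k contingency table
#'
#' @param tab Matrix (or table) of non-negative integer counts with positive
#'   row and column margins.
#' @return A `gfr_test_result` with the Pearson statistic and
#'   df = (r - 1)(k - 1); no continuity correction.
#' @examples
#' chi_square_test(rbind(c(20, 0), c(0, 20)))
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab))) {
    stopf("table must contain non-negative integer counts")
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) stopf("table must be at least 2x2")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stopf("table has a zero margin")
  E <- outer(rs, cs) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  res <- test_result(stat, stats::pchisq(stat, df = df, lower.tail = FALSE),
                     "chi_square", exact = FALSE)
  res$df <- df
  res
}

#' Bonferroni adjustment of a significance level
#'
#' @param alpha Family-wise level in (0, 1).
#' @param k Number of comparisons (>= 1).
#' @return `alpha / k` at full precision. Use [format_alpha()] for the
#'   conventional 4-decimal presentation (0.05 / 3 prints as 0.0167).
#' @examples
#' bonferroni_adjust(0.05, 3)
#' format_alpha(bonferroni_adjust(0.05, 3))
#' @export
bonferroni_adjust <- function(alpha, k) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stopf("`alpha` must be in (0, 1)")
  }
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stopf("`k` must be an integer >= 1")
  }
  alpha / k
}

#' @rdname bonferroni_adjust
#' @param level A significance level to present.
#' @export
format_alpha <- function(level) round(level, 4)
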