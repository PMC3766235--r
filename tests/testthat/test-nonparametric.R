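test_that("Wilcoxon signed-rank: exact enumeration cases", {
  r <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_true(r$exact)
  expect_equal(r$p_value, 0.25)      # 2/8 sign patterns reach the extreme
  expect_equal(r$statistic, 6)       # W+ convention

  r0 <- wilcoxon_signed_rank(c(0, 0))
  expect_true(r0$degenerate)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$statistic, 0)
})

test_that("Wilcoxon exact p matches enumeration oracle and stats::wilcox.test", {
  set.seed(51)
  for (i in 1:50) {
    n <- sample(3:10, 1)
    d <- round(rnorm(n, 0.3, 1), 3)
    d <- d[d != 0]
    if (length(d) < 1 || anyDuplicated(abs(d))) next
    r <- wilcoxon_signed_rank(d)
    expect_true(r$exact)
    expect_equal(r$p_value, oracle_wilcoxon_exact(d), tolerance = 1e-12)
    expect_equal(r$p_value,
                 suppressWarnings(stats::wilcox.test(d, exact = TRUE)$p.value),
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon asymptotic branch matches stats::wilcox.test without correction", {
  set.seed(52)
  for (i in 1:30) {
    n <- sample(13:60, 1)
    d <- rnorm(n, 0.2, 1)
    r <- wilcoxon_signed_rank(d)
    expect_false(r$exact)
    expect_equal(r$p_value,
                 stats::wilcox.test(d, exact = FALSE, correct = FALSE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("Mann-Whitney U: exact enumeration cases", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_true(r$exact)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3)
  # exchangeable groups -> p = 1 (with ties, falls back to the tie-corrected
  # asymptotic branch and still reports no evidence)
  same <- mann_whitney_u(c(5, 1, 3), c(3, 5, 1))
  expect_equal(same$p_value, 1, tolerance = 1e-12)
})

test_that("Mann-Whitney exact p matches oracle and stats::wilcox.test on n <= 12", {
  set.seed(53)
  for (i in 1:50) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- round(rnorm(nx, 0, 2), 3); y <- round(rnorm(ny, 0.8, 2), 3)
    if (anyDuplicated(c(x, y))) next
    r <- mann_whitney_u(x, y)
    expect_true(r$exact)
    expect_equal(r$p_value, oracle_mwu_exact(x, y), tolerance = 1e-12)
    expect_equal(r$p_value, stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney asymptotic branch matches stats::wilcox.test with ties", {
  set.seed(54)
  for (i in 1:30) {
    x <- sample(1:8, sample(8:25, 1), replace = TRUE)
    y <- sample(2:9, sample(8:25, 1), replace = TRUE)
    r <- mann_whitney_u(x, y)
    expect_false(r$exact)
    expect_equal(r$p_value,
                 suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                     correct = FALSE)$p.value),
                 tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis: closed-form case, degenerate case, oracle equivalence", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(r$statistic, 7.2)     # 12/(9*10) * (6^2+15^2+24^2)/3 - 30
  expect_equal(r$p_value, stats::pchisq(7.2, 2, lower.tail = FALSE))

  const <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_true(const$degenerate)
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)

  set.seed(55)
  for (i in 1:50) {
    groups <- lapply(1:sample(2:4, 1),
                     function(g) round(rnorm(sample(3:15, 1), g / 2), 2))
    r <- kruskal_wallis(groups)
    expect_equal(r$statistic, oracle_kw_H(groups), tolerance = 1e-10)
    kt <- stats::kruskal.test(groups)
    expect_equal(r$statistic, unname(kt$statistic), tolerance = 1e-10)
    expect_equal(r$p_value, kt$p.value, tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis post hoc applies Bonferroni-adjusted pairwise U tests", {
  set.seed(56)
  groups <- list(rnorm(20), rnorm(20, 2), rnorm(20, 4))
  ph <- kruskal_wallis_posthoc(groups, alpha = 0.05)
  expect_equal(ph$adjusted_alpha, 0.05 / 3)
  expect_equal(nrow(ph$pairwise), 3)
  expect_equal(ph$pairwise$p_value,
               vapply(list(c(1, 2), c(1, 3), c(2, 3)), function(ij) {
                 mann_whitney_u(groups[[ij[1]]], groups[[ij[2]]])$p_value
               }, numeric(1)))
  expect_true(all(ph$pairwise$significant == (ph$pairwise$p_value < 0.05 / 3)))
})

test_that("McNemar: exact binomial cases and the asymptotic branch", {
  expect_equal(mcnemar_test(1, 3)$p_value, 0.625)
  expect_equal(mcnemar_test(5, 5)$p_value, 1)
  expect_equal(mcnemar_test(0, 8)$p_value, 2 * 0.5^8)
  deg <- mcnemar_test(0, 0)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  # agreement with binom.test on the exact branch
  set.seed(57)
  for (i in 1:40) {
    b <- sample(0:12, 1); cc <- sample(0:12, 1)
    if (b + cc == 0 || b + cc > 25) next
    expect_equal(mcnemar_test(b, cc)$p_value,
                 min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5)),
                 tolerance = 1e-12)
  }
  # large discordance: continuity-corrected chi-square, matches mcnemar.test
  big <- mcnemar_test(30, 12)
  expect_false(big$exact)
  ref <- stats::mcnemar.test(matrix(c(5, 12, 30, 5), 2), correct = TRUE)
  expect_equal(big$statistic, unname(ref$statistic))
  expect_equal(big$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(mcnemar_test(-1, 2), "non-negative")
})

test_that("Pearson chi-square: closed forms and chisq.test equivalence", {
  expect_equal(chi_square_test(rbind(c(10, 10), c(10, 10)))$statistic, 0)
  expect_equal(chi_square_test(rbind(c(10, 10), c(10, 10)))$p_value, 1)
  r <- chi_square_test(rbind(c(20, 0), c(0, 20)))
  expect_equal(r$statistic, 40)
  expect_equal(r$df, 1)

  set.seed(58)
  for (i in 1:50) {
    tab <- matrix(sample(1:30, 6, replace = TRUE), 2, 3)
    r <- chi_square_test(tab)
    expect_equal(r$statistic, oracle_chisq(tab), tolerance = 1e-10)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(chi_square_test(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("Bonferroni adjustment divides the level and formats to 4 decimals", {
  expect_equal(bonferroni_adjust(0.05, 1), 0.05)
  expect_equal(bonferroni_adjust(0.01, 5), 0.002)
  expect_equal(format_alpha(bonferroni_adjust(0.05, 3)), 0.0167)
  expect_error(bonferroni_adjust(0.05, 0), "k")
  expect_error(bonferroni_adjust(1.2, 3), "alpha")
})

test_that("all tests keep p-values in [0, 1] on fuzzed inputs", {
  set.seed(59)
  for (i in 1:100) {
    d <- rnorm(sample(1:30, 1))
    expect_true(wilcoxon_signed_rank(d)$p_value >= 0)
    expect_true(wilcoxon_signed_rank(d)$p_value <= 1)
    x <- rnorm(sample(1:15, 1)); y <- rnorm(sample(1:15, 1))
    p <- mann_whitney_u(x, y)$p_value
    expect_true(p >= 0 && p <= 1)
  }
})
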