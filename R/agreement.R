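#' Paired differences between estimated and reference GFR
#'
#' Sign convention: positive differences mean the estimator reads higher than
#' the reference (`egfr - sgfr`), so a positive median difference is
#' overestimation.
#'
#' @param egfr Estimated GFR vector.
#' @param sgfr Reference GFR vector, positive, same length.
#' @return Numeric vector `egfr - sgfr`, order-preserving.
#' @export
gfr_differences <- function(egfr, sgfr) {
  check_same_length(egfr, sgfr, "egfr", "sgfr")
  if (length(sgfr) < 1L) stopf("need at least one pair")
  check_positive(sgfr, "sgfr")
  egfr - sgfr
}

#' Accuracy within a relative tolerance (P15/P30/P50 membership)
#'
#' A pair counts as accurate when `|egfr - sgfr| / sgfr < tol`, with a strict
#' inequality ("differing less than") and the reference GFR as denominator.
#'
#' @inheritParams gfr_differences
#' @param tol Relative tolerance in (0, 1), e.g. 0.30 for P30.
#' @return List with `count` and `pct` (= 100 * count / n).
#' @export
accuracy_within <- function(egfr, sgfr, tol) {
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0 || tol >= 1) {
    stopf("`tol` must be a single fraction in (0, 1)")
  }
  d <- gfr_differences(egfr, sgfr)
  count <- sum(abs(d) / sgfr < tol)
  list(count = count, pct = 100 * count / length(d))
}

#' Agreement summary: bias, precision and P15/P30/P50 accuracy
#'
#' The standard K/DOQI-style validation summary of one estimator against the
#' reference in one patient group: median signed difference with IQR (bias),
#' median absolute difference with IQR, and the counts/percentages of
#' estimates within 15%, 30% and 50% of the reference.
#'
#' @inheritParams gfr_differences
#' @param tolerances Accuracy tolerances; default `c(0.15, 0.30, 0.50)`.
#' @return An object of class `agreement_summary`: a list with `n`,
#'   `median_diff`, `diff_q1`, `diff_q3`, `median_abs_diff`, `abs_diff_q1`,
#'   `abs_diff_q3`, and per-tolerance `p<k>_count` / `p<k>_pct` entries.
#' @examples
#' agreement_summary(c(86, 60, 10), c(100, 100, 100))
#' @export
agreement_summary <- function(egfr, sgfr, tolerances = c(0.15, 0.30, 0.50)) {
  d <- gfr_differences(egfr, sgfr)
  qd <- quartiles(d)
  qa <- quartiles(abs(d))
  out <- list(
    n = length(d),
    median_diff = qd[2], diff_q1 = qd[1], diff_q3 = qd[3],
    median_abs_diff = qa[2], abs_diff_q1 = qa[1], abs_diff_q3 = qa[3]
  )
  for (tol in tolerances) {
    acc <- accuracy_within(egfr, sgfr, tol)
    key <- sprintf("p%d", round(100 * tol))
    out[[paste0(key, "_count")]] <- acc$count
    out[[paste0(key, "_pct")]] <- acc$pct
  }
  structure(out, class = "agreement_summary", tolerances = tolerances)
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("Agreement summary (n = %d)\n", x$n))
  cat("  median difference:     ", fmt_iqr(x$median_diff, x$diff_q1, x$diff_q3), "\n")
  cat("  median |difference|:   ", fmt_iqr(x$median_abs_diff, x$abs_diff_q1, x$abs_diff_q3), "\n")
  for (tol in attr(x, "tolerances")) {
    key <- sprintf("p%d", round(100 * tol))
    cat(sprintf("  P%-3d %3d (%.1f%%)\n", round(100 * tol),
                x[[paste0(key, "_count")]], x[[paste0(key, "_pct")]]))
  }
  invisible(x)
}

#' Bland-Altman analysis
#'
#' Mean difference, sample SD of the differences (n - 1 denominator), and the
#' 95% limits of agreement `mean_diff +/- 1.96 * sd_diff`. The per-pair
#' `(mean of the two methods, difference)` series is returned for plotting.
#'
#' @inheritParams gfr_differences
#' @return An object of class `bland_altman`: list with `n`, `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `loa_width`, and a data frame `points`
#'   with columns `avg` and `diff`.
#' @examples
#' bland_altman(c(99, 100, 101), c(100, 100, 100))
#' @export
bland_altman <- function(egfr, sgfr) {
  d <- gfr_differences(egfr, sgfr)
  if (length(d) < 2L) stopf("Bland-Altman needs at least 2 pairs")
  m <- mean(d)
  s <- stats::sd(d)
  structure(
    list(
      n = length(d),
      mean_diff = m, sd_diff = s,
      loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
      loa_width = 2 * 1.96 * s,
      points = data.frame(avg = (egfr + sgfr) / 2, diff = d)
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean diff %.2f, SD %.2f, 95%% LoA [%.2f, %.2f] (width %.2f)\n",
              x$n, x$mean_diff, x$sd_diff, x$loa_low, x$loa_high, x$loa_width))
  invisible(x)
}

#' CKD-stage concordance between an estimator and the reference
#'
#' Both GFR vectors are mapped through [stage_group()] and encoded ordinally
#' (I/II = 1, III = 2, IV/V = 3). Returns the per-patient stage difference
#' (estimated minus reference; negative values mean the estimator assigns a
#' LESS severe stage, i.e. a higher GFR band), a Wilcoxon signed-rank test on
#' those differences, and the 3x3 cross-classification table.
#'
#' @inheritParams gfr_differences
#' @return List with `stage_diff` (integer vector), `test`
#'   (a `gfr_test_result`), and `table` (3x3 contingency table,
#'   estimated x reference).
#' @export
stage_concordance <- function(egfr, sgfr) {
  check_same_length(egfr, sgfr, "egfr", "sgfr")
  check_positive(egfr, "egfr")
  se <- stage_group(egfr)
  sr <- stage_group(sgfr)
  diff <- as.integer(se) - as.integer(sr)
  list(
    stage_diff = diff,
    test = wilcoxon_signed_rank(diff),
    table = table(estimated = se, reference = sr)
  )
}
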