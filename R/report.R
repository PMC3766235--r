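#' Render a study report to disk
#'
#' Writes the machine-readable and human-readable artifacts of a study run:
#' `report.json` (full precision), `table1.tsv` (cohort characteristics),
#' `table2.tsv` (GFR medians and IQRs), `table3.tsv` (agreement summaries),
#' one `bland_altman_<estimator>.tsv` per estimator (per-patient mean vs
#' difference, plus the mean-difference and limit-of-agreement reference
#' lines), `model.json` (the trained RBF network) and `cohorts/*.csv`. The
#' TSVs round to 2 decimals; empty stage groups render as `-` and are noted
#' in `run.log`.
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Output directory (created if missing).
#' @param formats Any of `"json"`, `"tsv"`.
#' @return Character vector of written file paths, invisibly.
#' @export
render_report <- function(report, dir = report$config$output_dir, formats = c("json", "tsv")) {
  if (!inherits(report, "study_report")) stopf("`report` must be a study_report")
  if (is.null(dir)) stopf("no output directory given")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stopf("cannot create output directory '%s'", dir)
  written <- character()
  ests <- study_estimators()

  if ("json" %in% formats) {
    path <- file.path(dir, "report.json")
    jsonlite::write_json(report_as_list(report), path, auto_unbox = TRUE,
                         digits = I(17), null = "null", pretty = TRUE)
    written <- c(written, path)
  }

  if ("tsv" %in% formats) {
    groups <- c("overall", stage_levels())
    dash <- "-"
    f2 <- function(x) sprintf("%.2f", x)
    iqr <- function(row) if (is.null(row)) dash else fmt_iqr(row["median"], row["q1"], row["q3"])

    # Table 1: cohort characteristics
    t1 <- c(paste(c("variable", groups), collapse = "\t"))
    rowline <- function(label, f) {
      paste(c(label, vapply(groups, function(g) {
        cell <- report$cohort_table[[g]]
        if (is.null(cell)) dash else f(cell)
      }, character(1))), collapse = "\t")
    }
    t1 <- c(t1,
      rowline("n", function(cell) sprintf("%d", cell$n)),
      rowline("age_years_mean_sd", function(cell) sprintf("%.2f +/- %.2f", cell$age_mean, cell$age_sd)),
      rowline("male_n_pct", function(cell) sprintf("%d (%.1f)", cell$male_n, cell$male_pct)),
      rowline("female_n_pct", function(cell) sprintf("%d (%.1f)", cell$female_n, cell$female_pct)),
      rowline("alb_g_dl", function(cell) iqr(cell$alb)),
      rowline("scr_mg_dl", function(cell) iqr(cell$scr)),
      rowline("bun_mg_dl", function(cell) iqr(cell$bun)),
      rowline("sgfr_ml_min", function(cell) iqr(cell$sgfr)))
    p1 <- file.path(dir, "table1.tsv")
    writeLines(t1, p1); written <- c(written, p1)

    # Table 2: GFR medians (IQR) by method and stage
    t2 <- c(paste(c("method", groups), collapse = "\t"))
    for (m in c("sgfr", ests)) {
      t2 <- c(t2, paste(c(m, vapply(groups, function(g) {
        cell <- report$gfr_table[[g]]
        if (is.null(cell)) dash else iqr(cell[[m]])
      }, character(1))), collapse = "\t"))
    }
    p2 <- file.path(dir, "table2.tsv")
    writeLines(t2, p2); written <- c(written, p2)

    # Table 3: agreement summaries
    tols <- report$config$tolerances
    pk <- sprintf("p%d", round(100 * tols))
    hdr <- c("group", "estimator", "n", "median_diff_iqr", "median_abs_diff_iqr",
             as.vector(rbind(paste0(pk, "_n"), paste0(pk, "_pct"))))
    t3 <- paste(hdr, collapse = "\t")
    for (g in groups) {
      for (e in ests) {
        a <- report$agreement[[g]][[e]]
        row <- if (is.null(a)) {
          c(g, e, rep(dash, length(hdr) - 2))
        } else {
          c(g, e, sprintf("%d", a$n),
            fmt_iqr(a$median_diff, a$diff_q1, a$diff_q3),
            fmt_iqr(a$median_abs_diff, a$abs_diff_q1, a$abs_diff_q3),
            as.vector(rbind(
              vapply(pk, function(k) sprintf("%d", a[[paste0(k, "_count")]]), character(1)),
              vapply(pk, function(k) f2(a[[paste0(k, "_pct")]]), character(1)))))
        }
        t3 <- c(t3, paste(row, collapse = "\t"))
      }
    }
    p3 <- file.path(dir, "table3.tsv")
    writeLines(t3, p3); written <- c(written, p3)

    # Bland-Altman scatter data with reference lines
    for (e in ests) {
      b <- report$bland_altman[[e]]
      pe <- file.path(dir, sprintf("bland_altman_%s.tsv", e))
      lines <- c(sprintf("# mean_diff\t%.6f", b$mean_diff),
                 sprintf("# loa_low\t%.6f", b$loa_low),
                 sprintf("# loa_high\t%.6f", b$loa_high),
                 "avg\tdiff",
                 sprintf("%.6f\t%.6f", b$points$avg, b$points$diff))
      writeLines(lines, pe); written <- c(written, pe)
    }
  }

  pm <- file.path(dir, "model.json")
  save_rbf_model(report$model, pm); written <- c(written, pm)

  dir.create(file.path(dir, "cohorts"), showWarnings = FALSE)
  pt <- file.path(dir, "cohorts", "training.csv")
  pv <- file.path(dir, "cohorts", "validation.csv")
  write_cohort(report$training_cohort, pt)
  write_cohort(report$validation_cohort, pv)
  written <- c(written, pt, pv)

  pl <- file.path(dir, "run.log")
  writeLines(report$log, pl); written <- c(written, pl)

  invisible(written)
}

test_result_as_list <- function(x) {
  if (is.null(x)) return(NULL)
  list(statistic = x$statistic, p_value = x$p_value, method = x$method,
       exact = x$exact, degenerate = x$degenerate)
}

# full-precision, JSON-friendly view of a study_report (plot points and raw
# cohorts are carried by the TSV/CSV artifacts, not duplicated here)
report_as_list <- function(report) {
  ests <- study_estimators()
  strip_class <- function(x) if (is.null(x)) NULL else unclass(x)[setdiff(names(x), "points")]
  list(
    seed = report$config$seed,
    spread = report$config$spread,
    tolerances = report$config$tolerances,
    alpha = report$config$alpha,
    posthoc_alpha = report$tests$posthoc_alpha,
    n = as.list(report$n),
    cohort_table = lapply(report$cohort_table, function(cell) {
      if (is.null(cell)) NULL else lapply(cell, function(v) if (length(v) > 1) as.list(v) else v)
    }),
    gfr_table = lapply(report$gfr_table, function(cell) {
      if (is.null(cell)) NULL else lapply(cell, function(v) if (length(v) > 1) as.list(v) else v)
    }),
    agreement = lapply(report$agreement, function(g) {
      if (is.null(g)) NULL else lapply(g, function(a) unclass(a))
    }),
    bland_altman = lapply(report$bland_altman, strip_class),
    stage_concordance = lapply(report$stage_concordance, function(x) {
      if (is.null(x)) return(NULL)
      list(stage_diff = x$stage_diff, test = test_result_as_list(x$test),
           table = as.list(as.data.frame(unclass(x$table))))
    }),
    tests = list(
      wilcoxon_vs_reference = lapply(report$tests$wilcoxon_vs_reference, function(g) {
        if (is.null(g)) NULL else lapply(g, test_result_as_list)
      }),
      kruskal_wallis = lapply(report$tests$kruskal_wallis, function(k) {
        if (is.null(k)) return(NULL)
        list(test = test_result_as_list(k$test), adjusted_alpha = k$adjusted_alpha,
             pairwise = k$pairwise)
      }),
      mcnemar = lapply(report$tests$mcnemar, test_result_as_list),
      chi_square_accuracy = lapply(report$tests$chi_square_accuracy, test_result_as_list)
    ),
    log = report$log
  )
}
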