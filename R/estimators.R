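#' Re-expressed four-variable MDRD equation (eGFR4)
#'
#' Estimates glomerular filtration rate from serum creatinine, age, sex and
#' race using the re-expressed (IDMS-traceable creatinine) four-variable MDRD
#' equation:
#' \deqn{\mathrm{eGFR}_4 = 175 \cdot \mathrm{SCr}^{-1.154} \cdot
#'   \mathrm{Age}^{-0.203} \cdot 0.742^{[\mathrm{female}]} \cdot
#'   1.212^{[\mathrm{black}]}}
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param scr Serum creatinine, mg/dL. Values outside 0.1--30 mg/dL trigger a
#'   warning (a likely unit error; no micromol/L conversion path is provided).
#' @param age Age in years.
#' @param female Logical; `TRUE` for female subjects.
#' @param black Logical; `TRUE` for black subjects.
#' @return Estimated GFR, mL/min/1.73 m^2.
#' @seealso [egfr_mdrd6()], [stage_group()]
#' @examples
#' egfr_mdrd4(scr = 1.0, age = 50, female = FALSE, black = FALSE)
#' @export
egfr_mdrd4 <- function(scr, age, female = FALSE, black = FALSE) {
  check_positive(scr, "scr")
  check_positive(age, "age")
  warn_scr_units(scr)
  175 * scr^-1.154 * age^-0.203 * ifelse(female, 0.742, 1) * ifelse(black, 1.212, 1)
}

#' Re-expressed six-variable MDRD equation (eGFR6)
#'
#' Adds blood urea nitrogen and serum albumin to the four-variable equation:
#' \deqn{\mathrm{eGFR}_6 = 161.5 \cdot \mathrm{SCr}^{-0.999} \cdot
#'   \mathrm{Age}^{-0.176} \cdot \mathrm{BUN}^{-0.17} \cdot
#'   \mathrm{Alb}^{0.318} \cdot 0.762^{[\mathrm{female}]} \cdot
#'   1.18^{[\mathrm{black}]}}
#'
#' @inheritParams egfr_mdrd4
#' @param bun Blood urea nitrogen, mg/dL.
#' @param alb Serum albumin, g/dL.
#' @return Estimated GFR, mL/min/1.73 m^2.
#' @examples
#' egfr_mdrd6(scr = 1.0, age = 50, bun = 20, alb = 4.0)
#' @export
egfr_mdrd6 <- function(scr, age, bun, alb, female = FALSE, black = FALSE) {
  check_positive(scr, "scr")
  check_positive(age, "age")
  check_positive(bun, "bun")
  check_positive(alb, "alb")
  warn_scr_units(scr)
  161.5 * scr^-0.999 * age^-0.176 * bun^-0.17 * alb^0.318 *
    ifelse(female, 0.762, 1) * ifelse(black, 1.18, 1)
}

warn_scr_units <- function(scr) {
  if (any(scr < 0.1 | scr > 30)) {
    warning("serum creatinine outside 0.1-30 mg/dL; check units (this package uses mg/dL, not umol/L)",
            call. = FALSE)
  }
}

#' CKD stage grouping from GFR
#'
#' Maps GFR to the three-level KDOQI stage grouping used throughout the
#' package: stages I/II (GFR >= 60), stage III (30 <= GFR < 60), and stages
#' IV/V (GFR < 30), all in mL/min/1.73 m^2. "30--59" is read as the
#' half-open interval \[30, 60) so the three bands partition (0, Inf).
#'
#' @param gfr GFR values, mL/min/1.73 m^2; must be positive.
#' @return A factor with levels `c("I_II", "III", "IV_V")`.
#' @examples
#' stage_group(c(60, 59.9, 30, 29.999))
#' @export
stage_group <- function(gfr) {
  check_positive(gfr, "gfr")
  factor(ifelse(gfr >= 60, "I_II", ifelse(gfr >= 30, "III", "IV_V")),
         levels = stage_levels())
}

#' @rdname stage_group
#' @export
stage_levels <- function() c("I_II", "III", "IV_V")

#' Append closed-form eGFR columns to a cohort
#'
#' Computes `egfr4` and `egfr6` for every record of a cohort and returns the
#' cohort data frame with the two columns appended.
#'
#' @param cohort A `gfr_cohort` object (see [generate_cohort()]) or a data
#'   frame with columns `scr`, `age`, `female`, `black`, `bun`, `alb`.
#' @return The records data frame with `egfr4` and `egfr6` columns.
#' @export
add_mdrd_estimates <- function(cohort) {
  df <- cohort_records(cohort)
  df$egfr4 <- egfr_mdrd4(df$scr, df$age, df$female, df$black)
  df$egfr6 <- egfr_mdrd6(df$scr, df$age, df$bun, df$alb, df$female, df$black)
  df
}
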