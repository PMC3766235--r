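# gfrval

Method-comparison tooling for creatinine-based estimation of glomerular
filtration rate (GFR) in chronic kidney disease (CKD), for biostatisticians
and nephrology researchers who need a complete, reproducible
agreement-evaluation pipeline: estimators, reference-standard comparison
statistics, hypothesis tests, and seeded synthetic cohorts to run it all on.

## What it implements

**Estimators** (mL/min/1.73 m², serum creatinine in mg/dL):

* re-expressed four-variable MDRD:
  `eGFR4 = 175 · SCr^-1.154 · Age^-0.203 · 0.742^[female] · 1.212^[black]`
* re-expressed six-variable MDRD:
  `eGFR6 = 161.5 · SCr^-0.999 · Age^-0.176 · BUN^-0.17 · Alb^0.318 · 0.762^[female] · 1.18^[black]`
* an exact-design Gaussian RBF network mapping creatinine alone to GFR
  (one hidden unit per training point, `newrbe` kernel
  `exp(-(0.8326·|x-c|/spread)²)`, bias-augmented minimum-norm least squares).

**Agreement statistics** against a reference GFR (`sgfr`), per KDOQI stage
group (I/II ≥ 60, III [30, 60), IV/V < 30) and overall: median difference
and IQR (bias), median absolute difference, P15/P30/P50 accuracy (strict
`|eGFR − sGFR|/sGFR < tol`), Bland–Altman mean difference and 95% limits of
agreement, and CKD-stage concordance.

**Test battery**: exact (enumeration) and asymptotic Wilcoxon signed-rank,
Mann–Whitney U, Kruskal–Wallis with Bonferroni-adjusted pairwise post hocs,
McNemar on paired accuracy, Pearson chi-square — with flagged degenerate
results instead of errors in pipeline use.

**Synthetic cohorts**: seeded generator with a power-law SCr–GFR backbone
(`sgfr = shift · a · scr^(-b) · e^ε`), largest-remainder stage quotas, and
per-stage calibration to published population medians, so the entire study
runs with no patient data. See `vignette source in vignettes/` for the
modelling rationale and limitations.

## Worked example

```r
library(gfrval)

# closed-form estimator: 50-year-old non-black male, SCr 1.0 mg/dL
egfr_mdrd4(scr = 1.0, age = 50, female = FALSE, black = FALSE)
#> [1] 79.09466

# exact-design RBF: interpolates its training points
m <- rbf_train(c(1, 2, 4), c(80, 40, 20), spread = 1)
predict(m, c(1, 2, 3, 4))
#> [1] 80.00000 40.00000 19.12214 20.00000

# full study: train on a 327-patient general-CKD cohort, validate on a
# 207-patient diabetic-CKD cohort whose GFR runs 15% lower at the same SCr
rep <- run_study(study_config(seed = 1))
rep
#> GFR estimator validation study: n = 207 validation records (I_II 64, III 81, IV_V 62)
#>   egfr4    median diff  -1.91  P30  82.6%  LoA width   50.2
#>   egfr6    median diff  -2.81  P30  81.6%  LoA width   51.0
#>   egfr_rbf median diff   7.25  P30  65.7%  LoA width   46.3
```

Reading the output: the RBF network *overestimates* GFR in the shifted
validation population (positive median difference, here +7.25
mL/min/1.73 m² overall and in every stage group), but its differences are
*less dispersed* than either MDRD equation's — its Bland–Altman 95%
limits-of-agreement width (46.3) is smaller than eGFR4's (50.2) and
eGFR6's (51.0):

```r
rep$bland_altman$egfr_rbf
#> Bland-Altman (n = 207): mean diff 7.88, SD 11.81, 95% LoA [-15.27, 31.02] (width 46.29)

rep$agreement$I_II$egfr_rbf
#> Agreement summary (n = 64)
#>   median difference:      13.26 (0.79, 22.78)
#>   median |difference|:    18.20 (8.80, 23.73)
#>   P15   24 (37.5%)
#>   P30   45 (70.3%)
#>   P50   63 (98.4%)

format_alpha(bonferroni_adjust(0.05, 3))   # post hoc level across 3 stage pairs
#> [1] 0.0167
```

`render_report(rep, "report/")` writes `report.json` (full precision),
`table1.tsv`–`table3.tsv`, per-estimator Bland–Altman scatter TSVs,
`model.json` and the cohort CSVs. A command-line driver with the same
functionality lives in `exec/gfrval` (`run`, `simulate`, `evaluate`
subcommands).

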