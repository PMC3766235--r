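Package: gfrval
Title: Validation of Serum-Creatinine GFR Estimators Against a Reference Standard
Version: 0.1.0
Authors@R:
    person("GFR", "Validation Team", email = "gfrval@example.org", role = c("aut", "cre"))
Description: Tools for method-comparison studies of glomerular filtration rate
    (GFR) estimators in chronic kidney disease. Implements the re-expressed
    four- and six-variable MDRD equations, an exact-design Gaussian radial
    basis function (RBF) network mapping serum creatinine to GFR, KDOQI-style
    CKD stage grouping, and a full agreement-evaluation toolkit: median bias
    and IQR precision, P15/P30/P50 accuracy, Bland-Altman limits of agreement,
    CKD-stage concordance, and a nonparametric test battery (exact Wilcoxon
    signed-rank, Mann-Whitney U, Kruskal-Wallis, McNemar, Pearson chi-square)
    with Bonferroni adjustment. A seeded synthetic-cohort generator emulates
    diabetic CKD populations so the whole pipeline is testable without patient
    data, and a study driver reproduces the standard report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
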