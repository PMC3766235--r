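---
title: "Validating creatinine-based GFR estimators: models, statistics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating creatinine-based GFR estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfrval)
```

## The problem

Glomerular filtration rate (GFR) is the standard measure of kidney function,
but reference measurements (here, ^99m^Tc-DTPA renal dynamic imaging, treated
throughout as ground truth `sgfr`) are expensive and slow. Clinical practice
therefore relies on estimators computed from serum markers. This package
implements a complete method-comparison study for three such estimators in a
chronic kidney disease (CKD) population:

* **eGFR4** — the re-expressed four-variable MDRD equation,
  `175 * SCr^-1.154 * Age^-0.203 * 0.742^[female] * 1.212^[black]`;
* **eGFR6** — the re-expressed six-variable MDRD equation, which adds blood
  urea nitrogen (BUN) and serum albumin,
  `161.5 * SCr^-0.999 * Age^-0.176 * BUN^-0.17 * Alb^0.318 * 0.762^[female] * 1.18^[black]`;
* **eGFR_RBF** — a one-input exact-design Gaussian radial-basis-function
  (RBF) network mapping serum creatinine alone to GFR, trained on a general
  CKD population and validated on a distinct (diabetic) population.

Exponent signs in the six-variable equation follow the published re-expressed
form: negative for creatinine, age and BUN, positive for albumin. Serum
creatinine is mg/dL everywhere; there is deliberately no µmol/L conversion
path (silent unit bugs are worse than an explicit error), and inputs outside
0.1–30 mg/dL trigger a warning.

Patients are grouped by the KDOQI staging convention used for reporting:
stages I/II (GFR ≥ 60 mL/min/1.73 m²), stage III (30–59.99…), stages IV/V
(< 30). The printed range "30–59" is read as the half-open interval [30, 60)
so the three bands partition (0, ∞) exactly; `stage_group(60)` is I/II and
`stage_group(29.999)` is IV/V.

## The RBF network

The network follows the classical *exact design* (MATLAB's `newrbe`): one
hidden Gaussian unit per distinct training creatinine value plus an output
bias. Hidden-unit activation is `exp(-(0.8326 * |x - c| / s)^2)` with spread
`s`, so activation falls to 0.5 exactly at distance `s` — the `newrbe`
parameterization. The spread of the original study model is not published;
the default here is `s = 1` (the `newrbe` default), exposed as a parameter.

With `n` training points the bias-augmented design has `n` equations and
`n + 1` unknowns. Weights and bias are the **minimum-norm least-squares**
solution, computed by SVD. Three numerical choices matter:

1. **Singular-value truncation at `rcond = 1e-8`** (≈ √machine-epsilon,
   exposed as `rbf_train(svd_rcond = )`). Gaussian kernel matrices become
   numerically rank-deficient as soon as point spacing is small relative to
   the spread; singular values below `1e-8 · d_max` carry no numerically
   resolvable information, and keeping them amplifies target noise by more
   than 10^8, which makes off-sample predictions oscillate wildly. With the
   cutoff, well-separated training sets (gaps ≳ 0.5·spread, condition
   numbers ≲ 10^4 in practice) are still interpolated to ~10⁻¹³ relative
   error, while dense noisy training sets degrade gracefully into a smooth
   regression — the behaviour a GFR model actually needs. A consequence
   worth stating plainly: *exact interpolation of arbitrary targets is
   mathematically impossible in double precision once the design's condition
   number exceeds ~10^16*; no solver choice avoids that, so the
   interpolation guarantee is stated for the separated regime only.
2. **Near-duplicate merging.** Training inputs closer than 10⁻⁹ are merged
   to their target mean before the design is formed (duplicate creatinines
   with different reference GFRs make interpolation ill-posed). The merge is
   order-independent and logged in the model object (`n_merged`).
3. **No clamping, no default ridge.** Predictions are reported as computed
   (the study design is about quantifying bias, not hiding it). An optional
   ridge is available for experimentation and defaults to 0.

Trained on the noise-free 76-point grid `scr = 0.5, 0.6, …, 8.0` of the
curve `80/scr`, the network reproduces the curve at off-grid midpoints to
within 1% (the test suite asserts 2%).

## Agreement evaluation

All conventions are fixed once and used everywhere:

* **Differences** are `egfr - sgfr`: positive median difference =
  overestimation.
* **Bias** is the median difference with IQR; **precision** is the IQR of
  differences and the Bland–Altman limits-of-agreement width; **accuracy**
  is P15/P30/P50 — the percentage of estimates within 15/30/50% of the
  reference, with a *strict* inequality (`|d|/sgfr < tol`, reference in the
  denominator): an estimate off by exactly 30% does *not* count as within
  P30.
* **Quantiles** use linear interpolation between order statistics at
  position `1 + (n-1)p` (R's type 7), so all reported medians/IQRs are
  reproducible from the definition.
* **Bland–Altman** uses the sample SD (n−1) and the 1.96 multiplier; by
  construction `loa_width = 3.92 * sd_diff` to 10⁻¹².
* **Stage concordance** encodes the three stage groups ordinally (1, 2, 3)
  and applies the Wilcoxon signed-rank test to per-patient stage
  differences; negative differences mean the estimator assigns a less
  severe stage.

### Test battery

Exact small-sample versions are computed by complete enumeration: sign
patterns (2^n, n ≤ 12) for the Wilcoxon signed-rank, group assignments
(C(N, n_x), N ≤ 12, no ties) for the Mann–Whitney U, and the binomial tail
(b + c ≤ 25) for McNemar. Above those sizes the usual normal/chi-square
approximations with tie corrections apply, without continuity correction for
the rank tests (matching common statistical-package output). These
thresholds are implementation policy — the original analyses' software
internals are unknowable — and are exposed as arguments. Two-sided exact
p-values are twice the smaller tail, capped at 1. Degenerate inputs
(all-zero differences, no discordant pairs, constant groups) return flagged
results with p = 1 rather than raising, so a pipeline never falls over on a
constant subgroup.

The Kruskal–Wallis post hoc is pairwise Mann–Whitney at the
Bonferroni-adjusted level `alpha / 3` (reported as 0.0167 at 4 decimals for
`alpha = 0.05`). `bonferroni_adjust()` is literally `alpha / k`; note that
for k = 4 this is 0.0125.

Statistic conventions: the signed-rank statistic is W⁺ (sum of positive
ranks); the Mann–Whitney statistic is U for the first sample.

## The synthetic cohorts

No patient-level data are available, so the pipeline runs on seeded
synthetic cohorts whose *marginal* structure emulates the study populations.
The generator is a pure function of its spec (seed included).

**Backbone.** `sgfr = shift · a · scr^(-b) · exp(ε)`, `ε ~ N(0, σ_log²)`,
defaults `a = 80, b = 1`: an inverse power law is the natural family
(MDRD-type equations are power laws in creatinine) and puts `scr = 1` at
`sgfr = 80`. Noise is multiplicative lognormal with `σ_log = 0.18` — about
a 18% coefficient of variation, a realistic figure for the combined
biological and measurement scatter of reference GFR about a
creatinine-only curve; it is *not* a model of the isotope method's error
structure.

**Stage quotas** come from largest-remainder apportionment (207 patients at
proportions 0.309/0.391/0.300 give exactly 64/81/62). Within a stage,
creatinine is drawn from a lognormal truncated to the creatinine band the
backbone maps onto that stage's GFR band, and the record is resampled until
the noisy `sgfr` actually lands in the band (cap 1000 tries, then an
explicit infeasible-spec error — failing loudly beats silently distorting
the distribution).

**Calibration.** The validation spec (`n = 207`, shift 0.85) aims at the
published per-stage medians: SCr 0.77/1.58/5.19 mg/dL and sGFR
78.39/43.42/19.70 mL/min/1.73 m², each with an IQR band. A single power law
cannot pass through all six medians at once (the real SCr–GFR relation is
not exactly `68/scr`), and band truncation plus rejection bias shifts the
realized medians away from the sampling centers. The centers
(0.95, 1.57, 3.30 mg/dL; sdlog 0.22/0.25/0.30) were therefore chosen so the
*realized* per-stage medians of both SCr and sGFR fall inside their IQR
bands, which the test suite verifies across 20 seeds. Covariates: age ~
N(61.43, 12.03²) truncated at 18; 42.5% female; `black = FALSE` throughout
(the emulated populations are Chinese; the race factors remain implemented);
BUN and albumin lognormal around stage-specific medians from the published
table.

**The population shift.** The training spec (`n = 327`, shift 1.0) stands in
for the general-CKD population the network was originally fitted on; its
covariate structure is undocumented, so those defaults are declared
assumptions. The validation spec's `gfr_shift = 0.85` encodes the one
mechanism the study's discussion offers for the network's bias: at the same
creatinine, the validation (diabetic) population's measured GFR runs lower
than the training population's. A creatinine-only model trained on the
unshifted population then overestimates GFR in the shifted one — which is
exactly what the pipeline reproduces: positive RBF median difference in
every stage group, and a *smaller* Bland–Altman LoA width than either MDRD
equation (the MDRD estimates carry extra age/sex variance that the
creatinine-only network does not).

**What a green test establishes — and what it does not.** The synthetic
world reproduces the *qualitative* findings (direction of bias, ordering of
precision) and the marginal calibration targets. It does not reproduce the
published table values: those derive from 207 unavailable patient records,
and no generator tuned to marginals can recover joint structure such as the
true creatinine–GFR scatter shape, within-patient assay correlation, or the
exact accuracy percentages. Tests on synthetic cohorts validate the
machinery and the mechanism, not the paper-scale numbers.

## Pipeline conventions

`run_study()` stages are: cohorts → RBF training on (creatinine, reference
GFR) only → all three estimators on the identical validation records →
summaries and tests. Stage grouping for reporting always uses the reference
GFR, never an estimate. Errors propagate with a stage name
(`[training-cohort]`, `[rbf-train]`, …) and partial outputs are not
written. A study is deterministic given its config: cohort seeds are derived
from the master seed (training `seed`, validation `seed + 100000`), and two
runs of the same config render byte-identical reports. The JSON layer keeps
full precision (17 significant digits); the TSV tables round to 2 decimals
for reading.

## Known limitations

* One-input network only; no center selection, spread tuning or multi-input
  extension.
* The generator emulates marginals, not joint distributions; BMI/BSA are not
  generated.
* No confidence intervals on the limits of agreement.
* Exact-test size thresholds and the no-continuity-correction convention are
  package policy, documented above, not a reconstruction of any particular
  commercial package's internals.
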