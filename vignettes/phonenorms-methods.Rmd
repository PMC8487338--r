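---
title: "Methods: Equivalent-Score norming and psychometric validation for telephone screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Equivalent-Score norming and psychometric validation for telephone screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonenorms)
```

phonenorms implements the normative-standardization workflow used for the
cognitive section of the ALS Cognitive Behavioral Screen, Phone Version
(ALS-CBS-PhV): a short, motor-free executive screen for patients on the motor
neuron disease / frontotemporal spectrum, administered over the telephone.
This vignette documents the statistical model behind each stage, the
conventions adopted where the Equivalent-Score (ES) tradition leaves the rule
open, and what the synthetic-cohort generator does and does not emulate.

## 1. Demographic adjustment

Raw scores RS are regressed on transformed demographic covariates and
corrected relative to the sample mean of each transform:

$$AS = RS + \sum_j c_j \,\big(T_j(x_j) - \overline{T_j}\big).$$

The centering makes the identity exact: an examinee at the sample-mean
transformed demographics keeps their raw score. Adjusted scores are
real-valued and deliberately *not* clipped to the raw range — the ES bands
operate on the unbounded adjusted scale. The published ALS-CBS-PhV equations
(shipped in `inst/extdata/alscbs_phv_norms.json` and returned by
`published_norms()`) use `ln(100 − age)`, `age²`, or `age³` for age and
`ln(education)` or `sqrt(education)` for education. Note the direction: the
adjustment *adds* points with age and *removes* them with education, because
it compensates the performance expected at a demographic profile.

**Transform selection** (`fit_norm_equation()`). The norming tradition reports
"transformed age and education" without a selection rule, so the package uses
a deterministic one: per covariate, the candidate transform minimizing the
residual sum of squares in a single-covariate regression is selected
(candidates: identity, `ln(100 − x)`, `x²`, `x³` for age; identity, `ln x`,
`√x` for education), then the selected transforms plus a male indicator enter
a joint linear model.

**Predictor retention.** A covariate is kept when its joint-model p-value is
below α divided by the number of candidate transforms screened for it; sex,
which is not selected over candidates, is tested at α. The division is a
selection-aware Bonferroni guard: choosing the best of ~4 transforms by RSS
and then testing it at the nominal α would retain spurious predictors in
roughly a fifth of null cohorts. With genuine effects (|t| ≳ 4, as in
realistic norming samples) the correction costs essentially no power.

**Degenerate education.** Cohorts may contain education = 0. Fitting uses the
guards `ln(max(x, 1))` / `sqrt(max(x, 0))` (and fitted equations apply with
the same guards, so a derivation cohort can always be adjusted); *published*
equations are applied exactly as printed, and education = 0 with a
`ln(education)` term raises an explicit domain error, as does age outside
[18, 99].

## 2. Tolerance limits and Equivalent Scores

With n ranked adjusted scores, the outer tolerance limit oTL is the order
statistic at the largest rank $r$ such that
$P[\mathrm{Bin}(n, p) \ge r] \ge \gamma$, and the inner limit iTL at the
smallest $s$ with $P[\mathrm{Bin}(n, p) \le s - 1] \ge \gamma$ (defaults
$p = .05$, $\gamma = .95$), both found by exact enumeration of binomial
probabilities — no approximation. At n = 359 the ranks are 11 and 26; below
n = 59 no valid outer rank exists and `tolerance_limit_ranks()` fails loudly
with the minimum usable n.

The five-level scale is anchored at three distribution landmarks: ES 0 is
everything at or below the oTL ("defective"), ES 4 everything above the
sample median ("high-end normal"), and the span between is divided into
ES 1–3. **The intermediate rule is a documented choice**: the tradition
delegates the partition to its computational references without printing a
formula, so the package places the ES1/ES2 boundaries at the sample centiles
dividing the cumulative-probability interval $(p, .50]$ into three equal
parts — the 20th and 35th centiles — with the rank convention
$\lceil q\,n \rceil$ and ties resolved to the lower value. The rule lives in
one function so an alternative partition can be swapped without touching
callers, and every derived band table labels it. Classification
(`classify_es()`) treats printed interval endpoints as inclusive and flags
the zone of uncertain normality (oTL < AS ≤ iTL) as borderline.

The published ALS-CBS-PhV band tables are authoritative for patient scoring;
`derive_es_bands()` is for new cohorts and property tests and never
overwrites the fixture.

## 3. Reliability, validity, accuracy, equivalence

* **Screening.** Parametric vs non-parametric methods are chosen by the
  moment rule: non-parametric iff |skewness| ≥ 1 or |kurtosis| ≥ 3, with the
  *excess* kurtosis convention (normal = 0) so the |3| threshold matches
  common screening practice; both thresholds are strict ≥. Bonferroni family
  sizes are always caller-supplied and echoed, never inferred.
* **Cronbach's α** from the classical variance decomposition with n−1
  variances.
* **ICC** (`icc()`): single-measure, two-way random effects, *absolute
  agreement* — ICC(A,1) = (MSR − MSE)/(MSR + (k−1)MSE + k/n(MSC − MSE)) —
  for both test–retest and inter-rater designs. Absolute agreement is the
  conservative choice (it penalizes systematic rater/occasion shifts);
  the consistency form ICC(C,1) is available and every result carries its
  model label.
* **PCA** on the correlation matrix; loadings are variable–component
  correlations; components with eigenvalue > 1 are retained.
* **ROC** (`roc_vs_criterion()`): the positive class is a criterion score
  strictly below its sample 5th-centile order statistic; AUC by the
  Mann–Whitney midrank formulation (equal to the trapezoidal area under the
  empirical curve on tie-free data); SE by Hanley–McNeil with a normal CI
  truncated to [0, 1]. With heavily ceilinged criteria and small n the
  strictly-below split can be empty; the op errors, and the batch report
  records the stage as skipped.
* **TOST** (`tost_paired()`): two one-sided paired t tests against a
  symmetric interval. Bounds default to ±0.5 standardized differences mapped
  through the sample SD of the differences (the bounds were not printed in
  the source tradition, so they are explicit, overridable arguments); bounds
  may also be given on the raw scale, under which the one-sided t tests are
  exact and the type-I rate at the bound is exactly α. Both the TOST p (max
  of the one-sided p's) and the conventional paired t with two-sided p are
  reported, since reporting practice mixes them.
* **Power** (`power_regression_n()`): the overall regression test with
  numerator df u, denominator df v, noncentrality λ = f²(u + v + 1) and
  N = u + v + 1. The default rule solves the power equation in continuous v
  and rounds N — the convention of standard a-priori tools, and the one that
  reproduces the reference value N = 347 at u = 3, f² = .05, α = .05,
  power = .95 (integer search for the smallest never-under-powered N gives
  348 and is available as `rule = "integer"`).

## 4. Item calibration (2PL)

`fit_2pl()` estimates $P(\text{correct}) = \operatorname{logit}^{-1}(a(\theta - b))$
by marginal maximum likelihood with a standard-normal trait: EM over a fixed
grid of 41 equally spaced nodes on [−5, 5] with normalized normal weights
(doubling the node count changes estimates by < 1e−5 at desk scale). The
M step solves each item's weighted logistic regression by Newton–Raphson in
the logit-linear parametrization (a = c₁, b = −c₀/c₁). Convergence is a
maximum absolute parameter change below 1e−4; the marginal log-likelihood
trace is retained and non-decreasing; |a| > 10 is flagged as Heywood-style
divergence and non-convergence raises a condition carrying the partial fit.

Graded items are dichotomized at the item's 5th centile of ranked raw scores
(success = strictly above); error-count items are direction-reversed first so
success always codes better performance; zero-variance binary items are
dropped with a listing. Flags follow the conventional cuts — discriminative
a ≥ 1.5, highly discriminative a ≥ 1.7 (cumulative), difficult b ≥ 3. The
difficulty cut is a configurable convention inferred from reporting practice
rather than a universal standard, and is exposed as an argument.

## 5. The synthetic-cohort generator

`cohort_spec()` defaults emulate the published standardization sample:
n = 359, age ~ N(52.7, 15.75²) truncated to [18, 89] (rejection sampling,
rounded to integer years), education ~ N(13.06, 4.44²) on [0, 26], male
fraction 143/359. A latent cognitive-efficiency factor

$$g = \beta_0 + \beta_{age}\ln(100 - age) + \beta_{edu}\ln(\max(edu, 1)) + \varepsilon$$

drives every measure; each measure (the total included) is an independent
linear rescaling of g plus measure noise, rounded and clipped to its bounded
range. Because residual SDs and effect sizes are not published, the defaults
(β_age = 1.2, β_edu = 1.4, latent SD 0.8, and the intercept/slope/noise
table in `phv_measure_model()`) are **non-published choices** fixed once so
that the generated marginals match the reported ones: total ≈ 16.9 ± 2.7,
subtest means near the ceiling, criterion screens at 21.5 ± 0.96 and
34.9 ± 3, and age/education rank correlations of roughly −.4/.45. Sex never
enters the model, matching the reported absence of sex effects.

Repeats are built on the *latent* (pre-rounding) scale: the 30-day retest is
a bivariate-normal correlated copy hitting the target test–retest
correlation exactly before discretization; the second rater adds rounded
scoring noise to the observed score; the in-person format subtracts the
phone-minus-in-person shift (default +0.1 points) and adds noise. Item
responses use the rank-based inverse-normal transform of g as the trait, so
the generative trait distribution is exactly the standard normal the MML
calibration assumes — the generator is the exact inverse of the fit.

**What this does not emulate:** regional/occupational stratification, the
long irregular left tails of real criterion screens, floor-inflated item
distributions, and any dependence structure beyond a single latent factor.
Passing recovery tests therefore demonstrates estimator correctness under
the stated generative model, not robustness to real-data pathologies.

## 6. Numerical and design notes

* Deterministic seeding: every generator stage reseeds from the cohort seed
  plus a fixed stage offset, so any stage is reproducible in isolation and
  identical configurations yield byte-identical pipeline outputs.
* Near-ceiling bounded scores attenuate regression coefficients (censoring),
  which is a property of the data, not the estimator; recovery tests
  therefore use mid-scale intercepts (documented in the test helpers), while
  marginal-emulation tests use the defaults. Test problem sizes (e.g.
  n = 2000 cohorts, n = 3000 item calibrations, 5000-replicate TOST
  calibration) were chosen as the smallest giving stable Monte-Carlo
  margins.
* Degenerate inputs fail loudly everywhere a statistic divides by a
  variance: constant vectors, zero-variance items, incomplete two-way
  tables, collapsed ES bounds, and unattainable tolerance ranks all raise
  informative errors rather than returning numbers.
* The published-norms fixture is read-only and version-stamped; derived
  norms are always written to user-named files.

## 7. Known limitations

* The intermediate ES partition (20th/35th centiles) is a stand-in for an
  unpublished rule; band tables derived for new cohorts label it, and
  published tables are used verbatim for scoring.
* The 2PL module covers exactly the reported analysis: no 1PL/3PL, no
  graded-response model, no EAP trait export.
* No missing-data handling: reliability and IRT stages require complete
  tables by design.
* `fit_norm_equation()` assumes the candidate-transform list contains the
  true functional form; outside it, the minimum-RSS screen picks the best
  approximation without warning.
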