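---
title: "Measuring and decomposing income-related inequality in catastrophic health expenditure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and decomposing income-related inequality in catastrophic health expenditure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cheineq)
```

## The problem

Out-of-pocket (OOP) health payments can absorb so much of a household's
resources that they crowd out basic consumption. The standard indicator is
*catastrophic health expenditure* (CHE): a household incurs CHE when OOP
spending reaches a threshold share — conventionally 40% — of its *capacity
to pay* (CTP), operationalised here as non-food expenditure. Beyond the
level of CHE, the policy question is its distribution: if CHE concentrates
among poorer households, health financing is regressive in a way that
averages hide. This package implements the full measurement chain —
flagging, incidence, concentration curve and index, determinant
decomposition, heterogeneity strata, and regression robustness checks — for
balanced household panels of the kind produced by ageing-cohort surveys in
rural China.

## CHE flagging and incidence

`flag_che()` applies `CHE = 1{OOP/CTP >= t}` with `t = 0.40` by default.
Two conventions needed fixing:

* **Boundary**: a ratio exactly at the threshold counts as CHE. The
  indicator is defined by "40% or more", and an inclusive boundary keeps
  the flag monotone in OOP with no measure-zero ambiguity.
* **Degenerate denominators**: records with CTP ≤ 0 have an undefined
  ratio. They are excluded, counted, and reported (`n_excluded`), never
  silently dropped and never an error: real survey data contain such rows
  and a pipeline should quantify them.

Per-wave incidence is `n_che / n` with a normal-approximation 95% interval
`p ± 1.96·sqrt(p(1−p)/n)` clamped to [0, 1]; a Wilson interval is available
via `che_config(ci_method = "wilson")` for small samples, where the normal
approximation is known to undercover.

## Fractional ranks and the concentration index

`fractional_rank()` uses the **weighted midpoint convention**: sorting by
income, unit *i* gets rank `(cumulative weight before i + w_i/2) / W`. Tied
incomes receive their group's weighted midpoint, which is deterministic,
permutation-invariant, and keeps the weighted mean rank exactly 0.5 — the
property the covariance form of the index relies on. The raw order
statistic `i/N` is available as `mode = "order"` for sensitivity analysis,
but it is not the default: its mean is not 0.5 and it biases the index,
increasingly so at small *n*.

`concentration_index()` computes `C = (2/mu) * cov_w(Y, R)` with the
population-style (divide by total weight) covariance, under which three
algebraically equivalent forms agree to machine precision, and the test
suite holds them to 1e-10:

* the covariance form above;
* the direct sum `2/(n·mu) Σ Y_i R_i − 1` (equal weights);
* the slope of the "convenient regression" of `2·var(R)·Y/mu` on `R`.

The analytic standard error is taken from that regression slope — the
interval method for a concentration index is rarely stated in applied
studies, and the convenient-regression standard error is the common default.
A household-level percentile **bootstrap** (`bootstrap_ci()`) is provided as
the alternative; it re-ranks incomes within every resample (ranks are a
function of the sample, so resampling must recompute them), redraws
resamples whose outcome is all zero, and counts those redraws.

For a binary outcome the plain index is bounded by `|C| ≤ 1 − mu`. The
Wagstaff (`C/(1−mu)`) and Erreygers (`4·mu·C`) corrections are available
behind the `normalisation` argument and labelled in the output, but the
plain index is the default because it is what applied CHE studies report.

`concentration_curve()` aggregates tied ranks into single knots before
cumulating. This matters: the tie-averaged index corresponds to the
group-level polygon, and only with that aggregation does the quadrature
identity `C = 1 − 2·area` hold (the suite checks agreement to 1e-3 with
10^4 interpolation points). Endpoints (0,0) and (1,1) are set exactly.

## Decomposition

`decompose_cindex()` implements the regression-based decomposition for a
binary outcome. Because the outcome is a 0/1 flag, a linear probability
model is unattractive; a **probit** is fitted by maximum likelihood
(`glm.fit`, IRLS to epsilon 1e-10) and linearised through its marginal
effects:

```
C = Σ_j (b_j · x̄_j / mu) · C_j + residual
```

where `b_j` is the marginal effect of determinant *j*, `C_j` its
concentration index computed *by the same code path* against the shared
income ranks, and `b_j·x̄_j/mu` its elasticity. Design choices:

* **Average marginal effects** (mean of `phi(x_i'beta)·beta_j`) are the
  default; effects at covariate means are available (`me_type =
  "at_means"`). The AME is the modern convention and does not privilege an
  artificial "mean household" that no dummy configuration represents.
* **The residual is the remainder** `C − Σ contributions`. The alternative
  — a generalised concentration index of the probit residuals — agrees
  analytically, but the remainder form makes the decomposition identity
  hold to machine precision by construction, which the suite asserts at
  1e-10 for every fitted model.
* **Percent contributions** are emitted both raw (`contribution/C·100`,
  summing to `100 − residual%`) and rescaled to exclude the residual
  (summing to 100), since published tables are often ambiguous about which
  normalisation they print.
* **Dummy families** (economic-status quintiles, age bands) are declared
  explicitly so group totals are sums of member rows, exactly — the same
  aggregation used to check a published decomposition column for internal
  consistency in the test suite.
* Economic status is an income-quintile factor computed within the analysed
  sample, mirroring how applied studies construct it; its dummies are
  therefore deterministic functions of the ranking variable, and they are
  expected to absorb most of a purely income-driven gradient.

Degenerate designs are handled before fitting: constant columns and exact
linear combinations (e.g. a visit count identical to its use indicator in a
small sample) are dropped with a warning in the panel-facing wrappers, and
are hard errors in the low-level `fit_probit()` interface. Perfect
separation is detected as perfect classification (`max|y − p̂| < 1e-4`) and
reported with the offending column name.

## Regression robustness stages

`fit_che_logistic()` pools waves with wave fixed effects and reports
`exp(beta)` with Wald intervals. For a lone binary predictor the MLE odds
ratio equals the 2×2 cross-product ratio, which the suite checks to 1e-8.

`fit_quantile()` estimates conditional quantiles of household income given
the CHE flag and covariates — income on the left-hand side, deliberately
mirroring how this robustness check is reported in the applied literature,
not the usual causal direction. The pinball objective
`Σ ρ_τ(y − x'β)` is minimised by iteratively reweighted least squares on a
smoothed check loss with a decreasing smoothing parameter (from
`0.1·sd(y)` down to 1e-10), followed by a Nelder–Mead polish on the exact
loss; the suite verifies local optimality against 100 random coefficient
perturbations and exact interpolation on noise-free data. Intervals are by
household-cluster bootstrap (resampling households, not rows, respects the
panel dependence); bootstrap replicates warm-start from the point estimate
and skip the polish for speed.

## The synthetic-data generator

`generate_panel()` emulates the structure the analysis assumes, not any
particular household's microdata:

* **Income** is log-normal (default meanlog 9.5, sdlog 0.8, in currency
  units per year) with across-wave correlation 0.9 — right-skewed, with
  household persistence so the panel is meaningfully longitudinal.
* **CTP** is a non-food share of income, `N(0.55, 0.15)` clamped to
  (0.05, 0.95); food expenditure is the complement, so total expenditure
  equals income.
* **OOP** is zero with probability `1 − oop_base_rate` (default 0.85
  spend something), otherwise `CTP × Gamma(1.1, scale 0.11) ×
  exp(gradient·(log inc − meanlog) + covariate effects)`. Generating the
  *share of CTP* rather than a free currency amount is the key design
  decision: with `income_gradient = 0` and no covariate effects the OOP
  share is exactly independent of income rank, so the concentration index
  of CHE is zero in expectation — a sharp null the test suite exploits.
  A negative gradient (default −0.25) makes poorer households spend a
  larger share, producing pro-poor CHE inequality.
* **Covariates** are Bernoulli draws at the configured marginal
  prevalences (defaults from the emulated survey's baseline table, e.g.
  48.85% male heads, 66.52% chronic disease, 96.23% insured); age is a
  band (≤50, 51–60, 61–70, ≥71) with a continuous age uniform within the
  band that increments across waves, so the 65-year heterogeneity cutoff
  can be applied per wave. Head characteristics are drawn once per
  household; utilisation and income are redrawn per wave. Household income
  is treated as total (not equivalised), matching the quintile construction
  used downstream.
* One RNG stream per panel, seeded once: identical configuration and seed
  give a bit-identical panel, and the caller's RNG state is untouched.

The default magnitudes (gamma shape/scale, gradient, covariate effects)
were chosen once so that a default panel lands in the empirically
realistic regime for a rural ageing cohort — CHE incidence near 0.23 and a
concentration index near −0.13 — and are not tuned thereafter.

What the generator does **not** emulate: sampling weights, attrition and
re-contact (panels are exactly balanced), multi-member household rosters,
reporting error in expenditures, and any survey screening cascade. Passing
tests therefore demonstrate that the estimators are correct on data
satisfying the stated structure, not that any real survey satisfies it.

## Heterogeneity strata

`stratified_analysis()` supports the three standard splits (head aged ≥ 65
vs < 65; chronic disease; junior-high-plus vs elementary-or-below
education). Ranks are **recomputed within each stratum** before the index
and decomposition: a stratum's index should measure inequality within that
subpopulation, and the per-stratum decomposition is only internally
consistent against within-stratum ranks. Global ranks can be imposed by
computing the index directly with a precomputed `rank` vector if a
sensitivity analysis requires it. Empty or degenerate strata are skipped
with a warning naming them; complementary strata partition the includable
records, which the suite asserts.

## Numerical conventions and problem sizes

Tolerances asserted in the test suite: 1e-10 for agreement of the three
index forms and for the decomposition identity; 1e-3 for the curve–area
identity at 10^4 points; 3 standard errors for parameter recovery at
n = 50,000; binomial 4-sigma bands for generator marginals at n = 4,000.
Monte-Carlo exercises use 20 replicate panels of 20,000 households whose
seeds are spawned from a single master stream — consecutive integer seeds
produced visibly correlated generator streams, so replicate seeds are
always drawn, never incremented. These sizes keep the default suite under
a minute while leaving sampling error well below the asserted margins.

## Limitations

* The analytic index interval relies on the convenient-regression standard
  error, which ignores the sampling variability of the ranks; the bootstrap
  is the safer choice at small *n*.
* The probit decomposition linearises a nonlinear model; its residual
  absorbs the approximation error, and a large residual share is a signal
  to distrust the per-determinant attribution.
* The quantile solver is an interior smoothing method, not a simplex/LP
  solver: coefficients agree with the exact minimiser to the asserted
  objective tolerance, but at vertex-degenerate designs an LP solver would
  be preferable.
* Only the non-food-expenditure CTP base is implemented; subsistence-
  adjusted capacity to pay and expenditure-share CHE bases are out of
  scope, as are dominance tests between concentration curves.
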