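---
title: "Counterfactual births averted from survey microdata: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual births averted from survey microdata: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avertr)
```

# The estimand and the model

The package answers a counterfactual question at district level: how many
births did contraceptive use avert over the three years preceding a
fertility survey? The chain of reasoning has three stages.

**Stage 1 — observed rates.** Each district's total fertility rate (TFR) is
estimated directly from birth histories: women's exposure over the 36 months
strictly preceding the interview month is split exactly, in integer-month
arithmetic, across the seven 5-year age groups 15–19 … 45–49, and
age-specific rates are weighted births over weighted woman-years. TFR is
`5 × Σ ASFR`. The contraceptive prevalence rate (CPR) is the weighted
percentage of currently married women 15–49 using any method; couple-level
use is collapsed into the woman's single `using_any_method` flag, since the
package defines its own schema. All-women denominators are used for
exposure (the standard TFR definition); only the CPR is restricted to
women in union.

**Stage 2 — the cross-district law.** Across districts, log TFR is close to
linear in CPR, and logging also normalises the skewed TFR distribution, so
the model is

$$\log \mathrm{TFR}_i = \beta_0 + \beta_1\,\mathrm{CPR}_i + \varepsilon_i .$$

OLS gives the starting fit; because a handful of districts can carry gross
errors or idiosyncratic fertility regimes, the working fit is a robust
IRLS re-fit in which large-residual districts get small weights.

**Stage 3 — the counterfactual.** Setting CPR to zero while *preserving the
district's own residual* gives the potential TFR,
$\log \mathrm{TFRP}_i = \hat\beta_0 + \hat\varepsilon_i$, equivalently
$\mathrm{TFRP}_i = \mathrm{TFR}_i\,e^{c\,\mathrm{CPR}_i}$ with correction
slope $c = -\hat\beta_1$. The two forms are algebraically identical and the
test suite asserts their agreement to 12 decimals. Births averted and the
percentage increase in births follow as
$\mathrm{BA}_i = \frac{\mathrm{TFRP}_i - \mathrm{TFR}_i}{\mathrm{TFR}_i} B_i$
and $\mathrm{PIB}_i = 100\,\frac{\mathrm{TFRP}_i - \mathrm{TFR}_i}{\mathrm{TFR}_i}$,
where $B_i$ is the observed (weighted) birth count in the window. BA is
carried in the same unit as $B_i$; published tables in this literature
report it in thousands, and the package treats the "per 1000" phrasing of
the BA formula as that units annotation, not as a multiplier — the
published national rows satisfy `BA = (PIB/100) × B` exactly, which pins
the implemented formula.

**Two estimation variants.** Method 1 stratifies districts into four groups
by TFR (≤ / > a national-level threshold, default 2.2) × CPR (< / ≥ 50) and
fits one robust regression per group, on the argument that districts at
different phases of the fertility transition obey different local laws.
Method 2 fits a single pooled regression. Stratification is not innocuous:
because the groups are defined by the *observed* outcome, each stratum is a
truncated sample and its fitted slope is attenuated relative to the pooled
one (most visibly in the low-TFR/low-CPR group, where the pooled method
therefore yields systematically higher PIB — a property the tests
reproduce on synthetic data). With all four thresholds pushed outside the
data range, Method 1 collapses to Method 2 exactly.

**Aggregation.** State and national BA are plain sums of district BA, and
the aggregate PIB is recomputed as `100 × ΣBA / ΣB` — the births-weighted
mean of district PIBs, always inside their range. The reporting counts
("districts below replacement fertility", "districts with CPR above 50")
use strict inequalities at 2.1 and 50; these are deliberately distinct from
the 2.2/50 stratification thresholds of the fitting stage, and both sets
are configurable.

# The robust fit

The robust procedure is iteratively reweighted least squares in the style
of Stata's `rreg`, implemented in the package (the literature this method
comes from names "robust regression" without pinning a routine, so the
exact procedure is a documented design choice):

1. initialise at the OLS solution;
2. **Huber stage**: residual scale `s = median(|e − median(e)|) / 0.6745`
   (the normal-consistent MAD), weights `w = min(1, 1.345 / |e/s|)`,
   weighted least squares, iterate — the scale is refreshed every
   iteration;
3. **bisquare stage**: same loop with Tukey's
   `w = (1 − (u/4.685)²)²` for `|u| < 4.685`, else 0, starting from the
   Huber solution.

Convergence is a maximum coefficient change below `1e-8`, at most 50
iterations per stage; non-convergence returns the last iterate with
`converged = FALSE` and a warning rather than an error. The Huber stage is
convex and tames gross outliers; the bisquare stage can zero them out
entirely but needs the good start the Huber stage provides. Exposed
per-district weights and residuals make the down-weighting auditable
(`tidy()`, `glance()`, `autoplot()`), and `MASS::rlm` with a bisquare psi
serves as an independent cross-check in the test suite, agreeing with this
implementation to well under the differences that matter downstream.

Degenerate inputs are refused loudly: fewer than 3 districts, all-equal
CPR, nonpositive TFR, or robust weights collapsing below two distinct
design points all raise classed errors. If all residuals are (essentially)
identical the MAD scale is zero; the fit then keeps the current solution
with unit weights, which makes the robust fit equal OLS on noise-free data.
If a stratum's fitted slope comes out positive (so `c < 0` and PIB < 0),
the package warns and reports the negative value — transparency over
truncation, since silently flooring at zero would bias aggregates.

# The TFR confidence interval

Age-group birth counts are modelled as independent Poisson counts with a
log-exposure offset, one rate per group. On that model
`Var(log b̂_a) ≈ 1/b_a`, and the delta method gives

$$\mathrm{Var}(\log \mathrm{TFR}) = \frac{\sum_a r_a^2 / b_a}{(\sum_a r_a)^2},
\qquad r_a = b_a / E_a,$$

with groups without births contributing no variance information. The
interval `TFR · exp(±z · SE(log TFR))` is positive by construction and
asymmetric on the natural scale. This model-based interval is exact-in-form
for the synthetic generator (whose births are genuinely Poisson); on real
survey data it ignores clustering and stratification of the sample design,
which is out of scope here — weights are honoured, design variance is not.
Districts with no births at all return the degenerate interval (0, 0) with
a warning. Coverage is verified empirically: across 500 simulated districts
the 95% interval covers the true TFR at a rate inside [90%, 99%].

# What the synthetic generator emulates — and what it does not

The generator produces woman-level records with the essentials of a DHS
individual recode: century-month-code dates (CMC = months since January
1900), women 15–49 nested in districts nested in states, a
currently-married flag, an any-method use flag, and a sampling weight
(default 1). Its defaults are the study conditions the package is tested
under: 32 × 20 = 640 districts, district CPR uniform on 2.7–84.8 percent
(the observed all-India district range), the log-linear law with
β₀ = 1.2, β₁ = −0.0083, σ_ε = 0.1, interviews at CMC 1393 (January 2016),
and 75% of women currently married — a typical in-union share for women
15–49 in Indian survey data.

Mechanics worth knowing:

- Ages at interview are uniform over the 420 eligible months, hence uniform
  across the seven 5-year groups.
- Births over the 36-month window arrive as a Poisson process whose
  age-group rates follow a packaged normalized high-fertility shape
  (`asfr_shape_default`, peaking at 20–29) rescaled so `5·ΣASFR` equals the
  district's true TFR. No published age pattern is asserted — only the
  scaled total matters to the analysis.
- Only married women bear births, at rate `ASFR / married_fraction`, so
  *all-women* age-specific rates equal the target schedule and the
  estimator recovers the true TFR without a marital-composition correction.
  This mirrors the analysis' own framing that women outside union
  contribute neither contraceptive use nor births.
- Contraceptive use is an independent Bernoulli per married woman; the
  causal TFR–CPR link exists only at district level, which is exactly what
  the regression can see. No individual-level mechanism from use to
  fertility is simulated, because the method being tested never uses one.
- Reproducibility: one global seed; each district draws from a substream
  derived by stable hashing of (seed, district id, stage), so identical
  configurations are byte-identical and *adding* districts never perturbs
  existing ones.

What it deliberately does not emulate: household/cluster structure,
nonresponse, heaped or displaced birth dates, non-uniform age pyramids,
migration, method mix and use-effectiveness, or any within-district
heterogeneity in the TFR–CPR law. Passing tests therefore demonstrate that
the *pipeline arithmetic and estimators* are correct and recover a known
generating law — not that the log-linear law or the Poisson CI is adequate
for any particular real survey.

# Numerical and convention choices

- **Window**: the 36 months strictly before the interview month, excluding
  the interview month itself (the common DHS convention).
- **Ages**: completed years via integer CMC arithmetic,
  `floor((ref − dob)/12)`; an exact multiple of 5 goes to the older group
  (age 20 ⇒ 20–24). Eligibility uses age at interview; birth attribution
  uses age at the birth month. Exposure splitting is exact — a
  month-by-month brute-force accumulation is the test oracle and agreement
  is to machine identity, with no floating error in month counts.
- **Stratum ties**: "low TFR" is `tfr ≤ 2.2`, "high CPR" is `cpr ≥ 50`, so
  (2.2, 50) falls in group 3; thresholds are arguments.
- **Quantiles**: linear interpolation between order statistics (type 7);
  SD uses n − 1; the CV is `100·sd/mean`. Skew direction in the sensitivity
  summary is `sign(mean − median)`.
- **Undefined values**: a district with no married women gets CPR `NA`
  (flagged, excluded from fitting with a warning), not an error; CV with
  zero mean is `NA` with a warning; PIB/BA with `tfr ≤ 0` is an error.
- **Validation is total**: file readers enumerate every invariant
  violation with row numbers; nothing is silently dropped.

# Problem sizes in the test suite

The suite runs at sizes chosen to make Monte-Carlo assertions sharp but
cheap: exposure exactness on 1,000 random women; CI coverage on 500
districts of 200 women; slope recovery on the full 640-district frame
(noise-free to 6+ decimals, and within ±3 SE at σ_ε = 0.1); end-to-end
pipeline recovery on 200 districts of 150 women; robustness on a
constructed 100-district instance where one gross outlier moves the OLS
slope by more than 5% but the robust slope by less than 1%. The whole
suite completes in well under a minute.

# Known limitations

- The counterfactual assumes the other proximate determinants of fertility
  (marriage timing, breastfeeding, abortion, postpartum insusceptibility)
  are unchanged when contraception vanishes, and that current prevalence
  held throughout the reference window. Both are strong assumptions
  inherited from the method itself.
- Method mix is invisible: districts relying on highly effective methods
  are treated like districts with the same prevalence of less effective
  ones, understating averted births in the former and overstating them in
  the latter.
- The TFR CI is model-based (Poisson); survey-design variance is not
  propagated, and neither is the uncertainty of the fitted slope into BA —
  point estimates only, as in the underlying method.
- Stratified fits inherit truncation bias by construction; the package
  reports both methods side by side (plus `pib_distribution()` and
  `cv_of_ba()`) precisely so the disagreement is visible rather than
  averaged away.
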