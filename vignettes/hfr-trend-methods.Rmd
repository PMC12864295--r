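---
title: "Methods: censored imputation, breakpoint trends and regional mixed models for HFR egg monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censored imputation, breakpoint trends and regional mixed models for HFR egg monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfrtrends)
```

This vignette is the package's own account of the statistics it implements:
the models, the assumptions behind them, the tunable parameters, what the
synthetic generator does and does not emulate, and the numerical decisions a
maintainer would want spelled out.

## The analysis chain

Monitoring programmes for halogenated flame retardants (HFRs) in gull eggs
produce, for each colony and year, one to five pooled egg homogenates
measured for a panel of analytes (12 lower PBDE congeners plus BDE-190 and
BDE-209, alpha-HBCDD, and the two Dechlorane Plus isomers), each with a
method limit of detection (MLOD) that varies by analyte and year
(0.01–1.0 ng/g wet weight; 5.0 ng/g for BDE-209 in some analysis years).
The chain is: complete the censored records, sum analytes into the four
regulated classes (Σ₁₁PBDE, BDE-209, HBCDD, ΣDP), average pools into annual
colony means, ln-transform, fit a one-breakpoint trend per colony × class,
classify it against Stockholm Convention milestones, and compare regions
with a mixed model.

## Non-detect policy

For each colony × analyte group (pooled across years by default — the
detection rate is a property of a colony's record, and per-year groups are
often too small to fit; `impute_by_year` switches this):

* detection rate ≥ 50 % (inclusive — the boundary case imputes): fit a
  left-censored log-normal by maximum likelihood. Detected values enter the
  likelihood through the density, censored ones through the CDF at their own
  record's MLOD. The fit is a two-parameter Nelder–Mead optimization on
  (μ, log σ) started at the detected-value log moments; with no censored
  records it reduces to the closed-form MLE (mean and 1/n-variance of the
  logs), which is also the degenerate-data guard: identical values pin σ at
  a 10⁻⁶ lower bound and flag the fit.
* The m censored records receive the m smallest plotting-position quantiles
  exp(μ̂ + σ̂ Φ⁻¹(i/(n+1))), i = 1..m — so the completed sample lies on the
  fitted quantile–normal line. The i/(n+1) position is chosen for symmetry
  with quantile-normal plotting; nothing downstream is sensitive to the
  choice among standard plotting positions.
* Replacements are assigned in ascending order of a reference analyte
  measured on the same pools: BDE-99 for PBDE congeners, syn-DP for HBCDD
  and anti-DP. The reference map is made total by letting the two reference
  analytes reference each other (BDE-99 → syn-DP, syn-DP → BDE-99);
  reference analytes are completed first so dependents rank against
  completed values. Missing references fall back to deterministic
  year/pool-id order, flagged. Ties break by pool id so reruns are
  identical.
* A fitted quantile can exceed a record's MLOD under a poor fit; such
  replacements are clamped to the MLOD and flagged, and strict uniqueness is
  restored by nudging earlier values down by one part in 10⁹ — censored
  records must stay distinguishable and below their limit.
* detection rate < 50 %, fewer than 3 detected values, or a non-convergent
  fit: censored records are set to zero, loudly flagged in the audit table.
  Zero is not a concentration estimate; it is the programme's reporting
  convention for "mostly absent", and class means of all-zero colony-years
  are subsequently excluded from ln-scale trend fitting (`half_min_offset`
  substitutes half the minimum positive mean instead, off by default).

## Aggregation

Congeners enter the PBDE sum only if their study-wide detection fraction
reaches 3 % — re-derived from the data rather than hard-coded, so the
pipeline generalizes; under the programme's detection patterns BDE-190
drops out and the default panel reproduces the 11-congener sum. BDE-209 is
always analyzed separately (it proxies the commercial deca-BDE mixture).
Annual values are arithmetic means over pools (a single pool stands for its
year), and the log transform is applied to the mean.

Egg morphometrics are screened against class means by Pearson correlation,
falling back to Spearman when a Shapiro–Wilk test (α = 0.05; the test is a
package choice, the fallback rule is the programme's) rejects normality of
the linear-fit residuals. An exactly linear pair leaves numerically
degenerate residuals; that is treated as "normality not violated" rather
than an error. Screening is reported only — covariates never enter the
trend models, and the generic nested-model LRT in the mixed-model module
covers lipid-adjustment comparisons.

## Segmented trends

The model is y = β₀ + β₁·t + δ·(t − ψ)₊ with Gaussian errors (an
identity-link Gaussian GLM, i.e. least squares). Estimation is iterative
linearization: at a working ψ, regress on t, U = (t−ψ)₊ and V = −1[t>ψ],
and update ψ by γ̂/δ̂. Numerical decisions, each of which was measured
before freezing:

* **Damping.** The RSS profile in ψ is piecewise smooth with kinks at
  observed years, and its minimum can sit *at* a kink, where the plain
  update oscillates forever. Steps are halved when the update changes sign
  without shrinking; a proposed step leaving the observed range fails the
  run instead (that is divergence, not a boundary optimum).
* **Starts and convergence as evidence.** Deterministic starts at the
  observed-year tertiles. If no start converges to an admissible ψ the fit
  reports "no breakpoint" and the linear regression stands — mirroring how
  the field's standard tool behaves on uninformative series. An exhaustive
  profile-grid rescue exists behind `grid_fallback` but is off by default:
  taking the global profile optimum of a series where the iteration
  diverges makes the slope-change test select a breakpoint in roughly a
  quarter of pure-noise series (the maximally-selected-statistic problem),
  versus ~5 % for the default. This is the one place the package
  deliberately treats non-convergence as information.
* **Polish against the profile.** When at least one start converges, the
  profile grid (201 points over the admissible interval) is also evaluated,
  its optimum used as an extra start and as a candidate, and the lowest-RSS
  admissible candidate wins, ties toward the earlier ψ. Reported estimates
  therefore sit at the least-squares optimum; under simulation the fitted
  RSS matches an independent fine-grid search to grid resolution.
* **Admissibility.** At least `min_seg_points = 2` observed years strictly
  on each side of ψ, and at least `min_years_breakpoint = 6` years overall
  to attempt a breakpoint — short series go straight to the linear model.
* **Inference.** Slope SEs and t tests come from the working model
  *including* V, on n − 4 df: the V column carries the linearized
  breakpoint uncertainty, and dropping it understates slope variances
  (measured 95 % CI coverage rises from ~86 % to ~94 % under the recovery
  simulation). SE(ψ) = SE(γ̂)/|δ̂|. The reported "t value" of a fit is the
  first-segment slope test β₁/SE(β₁), matching the reporting convention of
  the programme's published tables; the slope-change test (δ) is reported
  alongside and is what gates model selection.
* **Selection.** Segmented replaces linear when AIC (k = 5 vs 3 — the
  breakpoint and σ count as parameters) is lower *and* the δ-test is
  significant at α; each component can be switched off. An exactly straight
  series (zero linear RSS) short-circuits to the linear fit, since
  comparing zero residual variances is meaningless. The decision trace is
  stored on the returned object.
* **Calendar years are used uncentred**, so slopes are ln-units per
  calendar year and ψ is a calendar year.

## Classification

Significant fits map to the five trend models: IT (post-breakpoint slope
positive), LI/NI/EI (negative post-breakpoint slope with ψ after listing /
between nomination and listing, both boundaries inclusive for NI / before
nomination), CT (significant linear trend), NS otherwise. ψ is compared as
a point estimate; its SE is reported but not used. For the PBDE sum the
registry keeps the earlier of the two commercial-mixture nomination years
(2005); all milestone years are a small CSV and can be overridden. Percent
annual change is (exp(β)−1)×100, magnitudes rounded half away from zero to
whole percent — the convention reproduces every published conversion.
Which p value gates classification of fitted series (`class_sig`) defaults
to the reported first-segment t, the printed-table convention; published
tables are classified with their printed p values, so the programme-level
tallies are criterion-independent.

## Regional mixed model

y_ijk = β₀ + β_Region(i) + u_ij + v_k + ε_ijk on colony-year ln means
(pool-level fitting is a data-preparation switch away, but means keep the
observation unit consistent with trend fitting). Sum-to-zero contrasts make
β₀ the overall mean and each region effect a deviation from it, so the
marginal-mean comparison of each region against the overall mean is the
test of β_Region(i) = 0; p values are reported unadjusted and
Holm-adjusted, since the programme specifies no multiplicity procedure.
Estimation is REML via lme4/lmerTest; Wald F for Region uses Satterthwaite
denominator df; the Region LRT refits both models by ML. Marginal means are
back-transformed by exponentiation — the interval of the *median* on the
raw scale, not the mean. Variance percentages are each component over the
sum of the three random components; fixed effects describe mean structure
and are not part of that total.

A calibration caveat measured during development: with 17 colonies in 4
regions, the ML LRT against χ²(3) rejects a true null about 10 % of the
time at α = 0.05 — the classical small-cluster anti-conservatism — while
the Satterthwaite F holds its level (~6 % in 300-rep simulation). Region
inference should therefore rest on the F test; the LRT is provided as the
model-inclusion screen it is used for in practice.

## The synthetic generator

`study_design()` defaults encode the programme's structure: 17 colonies
(10 Great Lakes + Niagara, 3 St. Lawrence, 2 Atlantic, 2 Arctic), years
2008–2023 with annual Great Lakes sampling, surveillance colonies annual
2008–2012 then alternate years, Arctic colonies from 2010; 1–5 pools per
colony-year drawn uniformly (the programme states the range, not the
distribution) of 2–15 eggs; region offsets +0.6/+0.8/−0.5/−0.9 ln-units
(urban–industrial basins high, remote regions low); shared year effects
with SD 0.3 ln-units per class; analyte/year MLOD schedule within
0.01–1.0 ng/g with BDE-209 at 5.0 in three years; BDE-190 generated at
2×10⁻⁴ of the class sum so it censors out, exercising the 3 % rule.
Pool values are piecewise-linear colony trends plus region offset, year
effect, colony-year deviate (`residual_sd`, default 0.25 — the published
tables do not report this, so it is a stated assumption, not an estimate)
and pool deviate (`pool_sd`, default 0.20, likewise a free parameter).
Class sums are split into analytes by fixed composition vectors (a typical
gull-egg congener profile) with common-factor composition noise of loading
ρ = 0.8, renormalized so sums are exact — only the sum matters downstream,
and ρ controls how tightly the reference analytes track their dependents.
A single seed governs everything; per-colony sub-seeds are derived by
hashing the colony id, so colonies are independent of design order.

What it does **not** emulate: chemistry QA/QC, between-batch re-analysis,
diet and migration processes, spatial covariance between colonies, or
temporal autocorrelation beyond the shared year effect. Passing recovery
tests on this generator shows the estimators invert the model they assume;
it cannot show the model captures every feature of field data.

## Problem sizes used in the test suite

The property suites run at sizes chosen to make Monte-Carlo bands tight
while keeping a default test run comfortable on one CPU: 500 series for
breakpoint recovery and null calibration (n_years = 14, ψ = 2015,
β₁ = 0.3, β₂ = −0.2, residual SD 0.2), 100 of them cross-checked against a
0.05-year profile grid; censored-ML recovery at n = 1000 censored at the
30th percentile; 200 replicates of the 17-colony × 12-year study for
variance-component recovery (true 20/10/70 %) and 300 for test calibration.

## Known limitations

One breakpoint at most per series; no autocorrelation-robust errors; no
Davies-type supremum test for the breakpoint (the selection rule's
calibration was instead verified by simulation); Kaplan–Meier and
regression-on-order-statistics alternatives to the censored-ML policy are
not implemented; zero-inflated colonies (detection far below 50 %) simply
drop out of trend fitting. The LRT caveat above applies to any analysis
with few colonies per region.
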