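---
title: "Methods: MoM normalisation and likelihood-ratio risk models for HDP screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MoM normalisation and likelihood-ratio risk models for HDP screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdpscreen)
```

This vignette is the package's account of its own methods: the models it
fits, the assumptions behind them, the parameters that matter, the
numerical conventions, and the design choices that were genuinely open.

## 1. The screening problem

Hypertensive disorders of pregnancy (HDP) — gestational hypertension
(GH), preeclampsia (PE) and severe preeclampsia (SPE) — are screened in
the first trimester (63–97 days, i.e. 9 weeks to 13 weeks + 6 days) from
a panel of four markers: serum D-dimer (ng/mL), PAPP-A (mU/L), free
β-hCG (ng/mL) and fetal nuchal translucency (cm).  The analysis is a
case-control design: marker distributions are contrasted between a
healthy control group and each case group (GH, PE, SPE, and the pooled
HDP group), and subjects are ranked by a likelihood-ratio risk score.

## 2. MoM normalisation

Marker concentrations vary strongly with gestational age and maternal
weight, so raw values are converted to multiples of the median (MoM).

**Gestational-age median.**  Each marker's population median follows a
log10-quartic in gestational age $t$ (weeks):
$$\mathrm{GA_{Med}}(t) = 10^{\,c_0 + c_1 t + c_2 t^2 + c_3 t^3 + c_4 t^4}.$$
Gestational age enters in *weeks* (days / 7): only with weeks does the
built-in D-dimer equation, coefficients
$(-108.6,\ 35.5,\ -4.253,\ 0.2262,\ -0.004508)$, produce medians of
plausible magnitude (≈ 231 ng/mL at 12 weeks, matching observed
first-trimester D-dimer levels); with days the exponent is astronomical.
Raw MoM is concentration / $\mathrm{GA_{Med}}$.

**Weight correction.**  The adjusted MoM further divides by a
dimensionless log-linear factor $10^{\,w_0 + w_1 \cdot \mathrm{weight}}$
normalised to equal 1 at the reference cohort's mean weight, so adjusted
and raw MoM coincide there.  The functional form of the production
weight equation used by screening laboratories is not published; we
adopt the log-linear first-order form as the default convention (a
higher polynomial degree is available via `weight_degree`).  We
deliberately interpret "adjust MoM by gestational age and maternal
weight" as the *composition of two separate dimensionless corrections* —
dividing the concentration by the GA median, then dividing the
resulting MoM by the weight factor.  A literal reading in which MoM is divided by
the *product* of the GA median and a weight median would apply the GA
median twice and have mixed units; we reject it as dimensionally
inconsistent and follow standard screening practice.

**Fitting.**  `fit_median_model()` estimates the quartic by ordinary
least squares of log10 concentration on gestational weeks over ≥ 50
control records spanning ≥ 3 distinct weeks, then regresses the log10
MoM residuals on weight and re-centres so the factor is 1 at the mean
control weight.  Because the median of a lognormal equals its geometric
mean, the OLS fit on the log scale targets the median directly, and the
median raw MoM of the reference cohort is ≈ 1 by construction.

**No extrapolation.**  A fitted model stores the gestational-age range
of its reference data, and `ga_median()` clamps evaluation into that
range.  Quartic polynomials diverge rapidly outside their fitting
support; without clamping, subjects whose gestational age falls below
the reference range would receive medians from an extrapolated
polynomial tail, which injects artefactual group differences whenever
case groups have slightly wider gestational-age envelopes than controls
(they do, in the emulated study).  The built-in D-dimer equation keeps
the full 63–97 day window.  Gestational ages outside the screening
window are a domain error, never extrapolated.

## 3. Likelihood-ratio risk models

For a marker subset $S$, the case group and the control group are each
modelled as multivariate Gaussian in the log10 adjusted MoM vector
(sample mean, unbiased sample covariance).  A subject with vector $x$
gets
$$\mathrm{LR}(x) = \frac{\mathcal N(x;\,\mu_{case},\Sigma_{case})}
                        {\mathcal N(x;\,\mu_{ctrl},\Sigma_{ctrl})},$$
evaluated in log space (Cholesky) and exponentiated, so $|\log LR|$ up
to ~700 cannot overflow.  Ten built-in marker subsets are fitted: the
four single markers, DD+PAPP-A, DD+free β-hCG, PAPP-A+free β-hCG,
DD+PAPP-A+free β-hCG, PAPP-A+free β-hCG+NT, and the full panel — each
for the four case definitions (GH, PE, SPE, pooled HDP).

**Scale.**  The default fits on log10 adjusted MoM.  MoM values are
positive and right-skewed, and the lognormal is the standard screening
assumption; fitting on raw MoM (`log_transform = FALSE`) is supported
for comparison.  Whether adjusted or unadjusted MoM feeds the models is
likewise configurable; adjusted is the default since adjustment is the
entire point of the weight/GA calibration.

**Maternal-age prior.**  The classical age-risk curve
$r(a) = 0.000627 + e^{-16.2395 + 0.286\,a}$ multiplies the likelihood
ratio.  The printed source of this formula carries a typographically
ambiguous trailing "−0.5"; three parses are implemented
(`canonical` — no trailing term, the classical aneuploidy form, the
default; `half_year` — age shifted by half a year; `trailing_term` — a
free −0.5 in the exponent).  All three are strictly increasing in age
and differ only by a constant factor on the exponential component, so
the choice never alters within-age ranking; it is deliberately
low-stakes.

**Risk convention and ranking.**  The published risk formula divides the
age prior by the likelihood ratio.  Taken literally, that number
*decreases* as the case likelihood rises, which would invert every ROC
curve.  We therefore separate reporting from ranking: `risk_hdp` is
reported under the as-printed reciprocal convention by default (the
identity `risk_hdp × LR = risk_age` holds exactly; a `direct`
product convention is available), while ranking, ROC construction and
cut-offs always use the score $\log_{10} LR$, for which larger = more
case-like.  This preserves the printed formula as a reporting quantity
while keeping AUCs above 0.5 achievable, as they are in the study being
emulated.

**Numerical safeguards.**  Covariances whose condition number exceeds
$10^{12}$ are ridged by adding $10^{-8}\,\mathrm{tr}(\Sigma)/d$ to the
diagonal; a marker with zero variance after regularisation is an error
naming the marker.  Density fits require ≥ 10 records per group.

## 4. Evaluation battery

`roc_curve()` builds the empirical ROC over all distinct score
thresholds (positive = score ≥ threshold; ties grouped, never
randomised).  The trapezoidal AUC is numerically identical (to $10^{-12}$,
tested) to the tie-corrected Mann–Whitney concordance probability.
Inference uses DeLong's covariance estimator by default (midrank
placements), with the Hanley–McNeil approximation behind
`ci_method = "hanley"` for comparison with legacy statistical software;
the p-value is the two-sided DeLong z-test of AUC = 0.5.

`youden_cutoff()` selects the threshold maximising sensitivity +
specificity − 1; ties are broken toward higher sensitivity (screening
favours detection) and then toward the lower threshold, so the rule is
deterministic.  `metrics_at_cutoff()` derives the full battery in closed
form: FPR = 1 − spec, FNR = 1 − sens, +LR = sens/FPR (an `Inf` sentinel
at specificity 1, serialised as `inf`), −LR = FNR/spec, and predictive
values at the *case-control mix*,
$\mathrm{PPV} = \frac{\mathrm{sens}\cdot n_{case}}
{\mathrm{sens}\cdot n_{case} + \mathrm{FPR}\cdot n_{ctrl}}$ (NPV
analogous).  Predictive values in a case-control design are
prevalence-dependent; the sample-mix convention is what makes the
published tables internally reproducible, and an external
`prevalence` parameter is available for population-scale estimates.

Group descriptives follow the emulated study's conventions: medians with
2.5/97.5 percentiles, a one-sample Kolmogorov–Smirnov normality check
per group (against a normal with the sample mean and SD — note this is
the legacy-software convention; with estimated parameters the test is
conservative), a tie-corrected Kruskal–Wallis test across the four
groups, and pairwise Mann–Whitney tests of each case group against
control.  No multiple-testing correction is applied, matching the
emulated analysis; this is a faithful reproduction choice, not a
statistical recommendation.

In the summary tables, cut-offs of single-marker models are translated
back to the adjusted-MoM scale by reporting the marker value of the
subject whose score sits at the operating threshold (with unequal group
variances the likelihood ratio is not globally monotone in the marker,
so a score threshold does not map to a unique MoM value; the
subject-at-threshold convention is deterministic and matches how
single-marker cut-offs are quoted in practice).  Multi-marker cut-offs
are reported as log10 likelihood-ratio scores.

## 5. The synthetic cohort: what it emulates and what it cannot

The study cohort (150 controls, 126 GH, 53 PE, 41 SPE) is not publicly
deposited, so `simulate_cohort()` generates stand-in cohorts that
reproduce the *published summaries*:

* Within each group, log10 marker concentrations are multivariate normal
  with per-marker mean = log10(published median) and
  SD = (log10 P97.5 − log10 P2.5) / (2 × 1.959964).  The lognormal is
  the standard model for screening markers and guarantees positivity.
  The published percentile pairs are mildly asymmetric about the median
  in log space; a three-number summary cannot determine a skewed family,
  so the symmetric inversion is used and the asymmetry is an irreducible
  approximation.
* Maternal age and weight are univariate lognormal fitted the same way
  from the published demographic summaries.
* Gestational age is discrete uniform over the 63–97 day screening
  window, clipped to each group's published percentile envelope —
  a maximum-entropy choice given that only a median and range are
  published.  The clipping piles probability on the envelope bounds, so
  the synthetic gestational-age *median* sits near the lower bound
  rather than at the published median; demographics are descriptive
  here and do not feed the risk models, so this artefact is accepted
  rather than hidden by an invented distribution shape.
* Between-marker correlations are **not published**.  The default is
  independence (identity matrix), configurable per group.  This is the
  largest structural gap between synthetic and real cohorts: real
  PAPP-A/free β-hCG correlations are material, and multi-marker AUCs on
  synthetic data will differ from real-data AUCs for this reason alone.
* `separation_scale` interpolates each case group's marker distribution
  toward control — both the log-median offset and the log-SD difference —
  so 1 reproduces the published separation and 0 is an exact null in
  which all groups share the control distribution (the calibration
  configuration used by the test suite).
* Group labels are assigned at generation; no clinical diagnostic
  process is modelled, and there is no missing data, no exclusion
  mechanism, and no twin/ART structure.

Consequently, passing tests demonstrate that the *pipeline* is correct
and calibrated (null AUCs ≈ 0.5, parameters recovered, orderings
reproduced), not that real first-trimester cohorts will show the
published AUC magnitudes.  The qualitative finding that D-dimer
discrimination strengthens with disease severity (SPE > PE > GH) is
reproduced on synthetic cohorts because it is driven by the published
medians and spreads themselves.

## 6. Problem sizes and tolerances used by the test suite

Chosen so each check is statistically decisive at desk scale: moment and
percentile recovery at n = 10,000 per group (Monte-Carlo error well
inside the 10% bands); null calibration at n = 10,000 per arm (AUC
standard error ≈ 0.004 against an acceptance band of ±0.05);
Kruskal–Wallis null uniformity over 200 replicates of n = 100 per group;
DeLong coverage over 1,000 replicates of 100 + 100; the
severity-ordering check over 100 seeds at ten-fold group sizes; the
median-curve recovery at n = 5,000 with fixture noise SD 0.05 log10, at
which the estimator's edge sampling error is several-fold smaller than
the 2% recovery band.  Exact identities (AUC vs pair counting, metric
algebra, likelihood-ratio affine invariance) are asserted at $10^{-12}$
to $10^{-8}$.

## 7. Known limitations

* No truncation of extreme MoM values (commercial risk engines truncate;
  the emulated analysis does not describe any).
* No calibration of absolute risk to population incidence — reported
  risks are relative quantities under the study's case-control mix.
* The NT median machinery is assumed identical to the serum markers';
  the emulated study reports NT MoM without printing an NT median
  equation.
* The quartic gestational-age median is an interpolation model; its
  clamped evaluation outside the reference range is a constant
  continuation, not a biological claim.
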