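---
title: "Methods: circulating miRNA qPCR biomarker analysis for MetS in PCOS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circulating miRNA qPCR biomarker analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcosmir)
```

## Scope and model

`pcosmir` implements the statistical core of a serum circulating-miRNA
biomarker study in a three-group case-control design: healthy controls and
polycystic ovary syndrome (PCOS) patients stratified into normoandrogenic and
hyperandrogenic subgroups by serum free testosterone. The measurement
platform it models is a qPCR low-density array (up to 750 assays per sample,
one Ct value per assay and sample). The pipeline runs:

1. Ct parsing and detection filtering,
2. global mean normalization and 2^-ddCt relative quantification,
3. clinical derivations (free testosterone, HOMA-IR, metabolic syndrome),
4. covariate-adjusted differential and correlation statistics,
5. ROC analysis of single markers and a logistic multi-marker panel.

All stages operate on the log2 (cycle) scale where the qPCR measurement
process is approximately additive: one cycle equals one doubling, so a linear
fold change `f` appears as a Ct shift of `-log2(f)` cycles.

## Preprocessing

**Detection rule.** An assay is kept when it is detected (Ct present and at
or below the detection limit, default 35 cycles) in at least
`max(min_samples, ceiling(min_fraction * n_samples))` samples; defaults are
10 samples and 15%, the customary inclusion rule for serum arrays of this
size. Platforms report "undetermined" rather than a cycle cutoff, so the
limit is configurable; wells above it are treated as undetected everywhere.

**Global mean normalization.** Each sample's normalization factor is the
arithmetic mean Ct of its detected, filter-passing assays; `dCt = Ct - mean`.
This removes any per-sample additive offset (input amount, pipetting)
*exactly*, which is the main argument for the global mean over a single
reference assay when hundreds of assays are measured. Whether the original
method used each sample's own detected set or a common set across samples is
ambiguous in practice; both are implemented (`per_sample_detected`, the
default, and `common_detected`) and give identical results on complete data.

**Relative quantities.** `rq = 2^-(dCt - mean(dCt over reference samples))`.
The geometric mean of `rq` over the reference (calibrator) group is exactly 1
per assay; group fold changes are computed as `2^(difference of log2 means)`.

**Variability.** `assay_cv()` computes SD/mean. The scale matters: on linear
relative quantities a biological spread of 1 cycle corresponds to a CV of
roughly 70%, whereas on the Ct scale the same spread around a mean of ~25
cycles is a CV under 5%. Published "<5% CV" figures for serum arrays are only
consistent with the latter, so the scale is a parameter (`"rq"` default,
`"ct"` available) and is recorded in the output.

**Reference stability.** `normfinder_stability()` ranks candidate normalizer
assays by a variance decomposition in the spirit of model-based
reference-gene selection: after optional per-sample centering (which makes
the score invariant to sample-loading shifts), each assay gets a pooled
within-group variance and a sample-size-weighted squared between-group
deviation; the stability value is `sqrt(intra + inter)` in cycles, lower =
better. This is a transparent variant rather than a line-by-line
reimplementation of the original estimator (which adds shrinkage of the
group differences); for the ranking task on tens of candidate assays the two
agree in ordering, and the simple estimator is exactly reproducible by a
brute-force oracle, which the test suite exploits.

## Clinical derivations

**Free testosterone** solves the two-ligand mass-action equilibrium with
SHBG (association constant 1e9 L/mol) and albumin (3.6e4 L/mol, linear
binding; albumin defaults to 43 g/L because it is rarely measured in these
cohorts). The closed-form positive quadratic root is returned and satisfies
the mass balance to 1e-9 relative; the function is strictly increasing in
total T and decreasing in SHBG.

**HOMA-IR** is `insulin [mU/L] * glucose [mmol/L] / 22.5`.

**Metabolic syndrome** follows the IDF female rule: at least three of waist
>= 80 cm, BP >= 130/85 mmHg, glucose >= 5.6 mmol/L, HDL < 1.3 mmol/L,
triglycerides >= 1.7 mmol/L. Comparisons are implemented exactly as printed
(>= for elevated criteria, strict < for HDL); any missing component makes
the call indeterminate with the missing fields named, rather than guessing.

**Androgen stratification** labels PCOS subjects hyperandrogenic when free T
is strictly above 0.034 nmol/L (a reference 95th percentile for women); a
value exactly at the threshold is normoandrogenic. The strictness convention
is a documented choice — the boundary has probability zero under any
continuous model, but ties must resolve deterministically.

## Statistics

Group comparisons use Student's t (equal-variance, matching the named test;
Welch by flag) and one-way ANOVA with Tukey HSD on log2 relative quantities.
Covariate adjustment (age and BMI by default) is done with per-assay binary
logistic regression (case/control) and baseline-category multinomial
logistic regression (three groups, controls as baseline), reporting odds
ratios per log2 unit with Wald 95% CIs. Both the unadjusted test p-value and
the adjusted OR are reported side by side, because they answer different
questions. The multinomial model is fitted in-package by BFGS on the exact
log-likelihood with analytic gradient (no suitable pre-installed backend);
with two categories it agrees with `glm(binomial)` to 1e-5, which the tests
check.

Complete separation in any logistic fit is flagged (`"separation"`) and the
OR reported as non-estimable; the fitted score is still returned where a
ranking remains meaningful (ROC panels). Missing data policy: pairwise
complete for correlations (n reported per pair), complete case for
regressions.

Normality is screened with a one-sample Kolmogorov-Smirnov test against a
normal with estimated parameters — the classical software default, whose
p-value is conservative; a Monte Carlo Lilliefors correction is available and
is what the calibration tests use. No multiple-testing adjustment is applied
by default (the design is exploratory and the assays strongly correlated);
Benjamini-Hochberg columns are available by flag.

Partial Pearson correlations are computed by residualizing both variables on
`[1, covariates]`, with a t reference on `n - k - 2` degrees of freedom; the
single-covariate closed-form recursion is used as the test oracle.
`power_two_sample_t()` uses the noncentral t distribution with noncentrality
`d * sqrt(n1 n2 / (n1 + n2))`, handling unequal groups.

## ROC and panels

The empirical ROC is evaluated at every distinct score; AUC is the
Mann-Whitney statistic (ties count one half), identical to the trapezoidal
area. Confidence intervals default to the DeLong placement-variance method,
with a stratified bootstrap alternative; paired AUC comparisons use the
paired DeLong test. Single-marker ROCs in the pipeline use automatic
orientation (AUC >= 0.5) because a marker's sign is not known a priori; the
orientation is recorded.

Panels are in-sample maximum-likelihood logistic combinations of the marker
log2 values — matching how such panels are typically reported — with
leave-one-out cross-validated scores available because in-sample AUC with 3
predictors on ~40 subjects is optimistic. Operating points default to the
Youden index with ties broken toward higher specificity; fixed-sensitivity /
fixed-specificity rules are provided. With 7 positive cases an empirical
sensitivity is necessarily a multiple of 1/7, so printed operating points
that are not such multiples cannot be reproduced from confusion counts; the
package reports the counts themselves.

## The synthetic cohort generator

Because the motivating data are not deposited, `cohort_config()` defines a
stated world with the structure the analysis assumes, and every downstream
stage is tested against it:

- 62 subjects (20 controls, 23 normoandrogenic, 19 hyperandrogenic PCOS),
  750 assays of which 303 are detectable in serum (40.4%);
- Ct values are `base + sample offset - log2(group fold) - log2(MetS fold) +
  correlated noise`; undetectable assays sit near the detection limit and
  are missing at random with per-assay detection probabilities below 5%;
- planted group effects of 1.2-2.9x on named markers; three markers carry
  additional MetS-linked shifts (about 2, 1.4 and 1.2 cycles) so the panel
  stage is exercised end to end with single-marker discrimination in the
  AUC 0.8-0.92 range at the default noise;
- biological + technical noise of 1.0 cycle SD per well — large enough that
  2-3x fold changes do not trivially separate groups, and consistent with a
  sub-5% CV *on the Ct scale*; per-sample loading offsets of 0.5 cycles SD,
  which normalization must (and does, exactly) remove;
- two correlated clusters (30 and 11 assays, within-cluster r = 0.6 via a
  shared latent factor) mimicking the strong intercorrelation of abundant
  circulating miRNAs;
- clinical variables drawn per group from log-normal (skewed variables,
  parameterized by median and IQR) or normal (symmetric, mean and SD)
  families with the location/scale structure of the study's baseline table.
  Waist circumference and blood pressure are not tabulated there, so their
  defaults were chosen once to be clinically realistic and to reproduce the
  reported metabolic-syndrome prevalence through the classification rule
  itself (about 1/20 controls and a third of the hyperandrogenic group) —
  prevalence is an emergent property of the distributions, never a planted
  label.

What the generator does *not* emulate: correlations between clinical
variables (they are drawn independently within groups), plate/position
effects, pre-amplification chemistry, and the exact distribution families of
the real cohort (only medians/IQRs or means/SDs are published; log-normal is
the default for skewed variables). A green test therefore establishes that
the pipeline recovers what was planted under the stated noise model — not
that the original cohort's specific estimates are reproduced.

Two consequences of the stated world are worth knowing. First, because the
planted stratum determines the hormone distributions but stratification is
recomputed from generated free T, about 10-20% of PCOS subjects land in the
other stratum than planted — as in reality, where the stratification is
itself a measurement. Second, markers strongly *down*-regulated in MetS
cases can push those subjects' Ct values past the detection limit:
informative missingness that occasionally leaves a marker (or the whole
panel) non-estimable in a small cohort. The pipeline records such stages as
skipped instead of failing.

## Numerical choices

- Centering and geometric-mean invariants hold to 1e-9 (they are exact up to
  floating-point roundoff).
- The Fisher exact p sums hypergeometric probabilities `<= p_obs * (1 +
  1e-7)`, the standard tolerance for "no more probable than observed";
  the odds ratio is the conditional MLE solved by `uniroot` on the log scale.
- Separation detection combines the IRLS warning, a residual deviance near
  zero, and coefficient magnitude (>15 per log2 unit).
- ROC ties: a positive-negative score tie contributes 1/2 to the AUC;
  operating-point ties resolve toward higher specificity.
- Seeds: every generator takes its seed from the config; derived seeds stay
  below 2^31.

## Limitations

The package deliberately excludes wet-lab concerns (RNA extraction, reverse
transcription, pre-amplification), the Rotterdam diagnosis itself (group
labels are inputs), inter-plate calibration, missing-Ct imputation, and
penalized panel selection. In-sample panel AUCs on small cohorts should be
read alongside the leave-one-out scores the package also provides.
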