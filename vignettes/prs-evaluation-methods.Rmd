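---
title: "Methods: standardised evaluation of polygenic risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardised evaluation of polygenic risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsbench)
```

## The problem

Polygenic risk scores (PRSs) summarise an individual's common-variant
genetic liability for a disease or a quantitative trait as a single number.
Reported PRS performance depends heavily on evaluation choices — the metric,
the covariates, the cohort composition, phenotype definitions, ancestry of
the evaluated subgroup — which confounds comparisons between scores.
`prsbench` implements a standardised evaluation pipeline: given
per-individual scores (computed upstream; genotype handling is out of
scope), a cohort table, phenotype tables and optionally rare-variant
carrier status, it produces a like-for-like performance report, and a
seeded synthetic-cohort generator stands in for restricted biobank data so
that every analysis is testable end to end.

## Effect metrics

All effects are *per standard deviation of the PRS*. The raw score is
standardised by the affine map estimated in the evaluation subgroup (by
default the ancestry group being analysed, so "per SD" is
ancestry-specific):
$z_i = (x_i - \bar{x}) / \hat\sigma$, where $\hat\sigma$ is the population
(denominator-$n$) SD, so the standardised reference has SD exactly 1. The
descriptive distribution tables use the usual $n-1$ denominator; at cohort
sizes the two conventions are indistinguishable, and all per-SD estimates
are invariant to rescaling the raw score by construction.

* **Disease traits.** The odds ratio per SD comes from maximum-likelihood
  logistic regression of case status on $z$, adjusting for age at first
  assessment and sex (sex is dropped automatically for sex-restricted
  traits); the hazard ratio per SD from a Cox model with Breslow tie
  handling (switchable), either on the age timescale (entry at birth for
  lifetime analyses, left truncation at assessment for incident ones) or
  on the follow-up timescale. Confidence intervals are Wald, on the log
  scale. Complete separation and non-convergence are errors, never silent
  estimates (IRLS/Newton tolerances 1e-8/1e-9, 100 iterations).
* **AUC** is the Mann–Whitney concordance of the PRS alone (no
  covariates), ties counted 0.5, with a DeLong analytic 95% CI by default
  and a percentile bootstrap as an option.
* **Quantitative traits.** The trait is standardised to zero mean and unit
  variance and regressed on $z$ by ordinary least squares with age and sex
  adjustment; for sex-stratified reporting the trait is standardised
  within each sex separately and then pooled, which changes the effect
  scale and is labelled as such in the report. The reported $r^2$ is
  *incremental*: the gain in model $R^2$ from adding the PRS to the
  covariate-only model (the marginal variant would also include covariate
  effects, which is not a property of the score).
* **Effective sample sizes** for case-control designs use
  $4\sum_j n_j c_j (1-c_j)$ across constituent studies and
  $4/(1/n_0 + 1/n_1)$ for a single study; the two agree exactly on a
  single component.

Metrics are gated on case counts: an estimate is reported only when at
least 100 cases (configurable) are available, otherwise the entry keeps its
counts and a gating reason but no estimate. Small or ancestry-rare diseases
therefore appear explicitly as gated rather than vanishing.

## Cumulative incidence by PRS band

Individuals are ranked by score ("$\le$" empirical CDF, ties broken by
stable id order so the assignment is deterministic and order-independent)
and grouped into percentile bands, by default the top 3%, the median
40–60% and the bottom 3%. Each band gets a Kaplan–Meier cumulative
incidence curve on the age axis, $1 - \hat S(a)$, with Greenwood variance
and complementary log-log 95% intervals (bounds stay inside $[0,1]$).

Two entry conventions are exposed and recorded in the report: *lifetime*
(entry at age 0, retrospective diagnoses included — appropriate for
conditions diagnosed before cohort entry, e.g. childhood-onset diabetes)
and *incident* (left truncation at the assessment age, prevalent cases
excluded). Death and loss to follow-up are treated as independent
censoring; this is a Kaplan–Meier, not an Aalen–Johansen, estimator, so
band risks are interpretable as risk in the absence of competing death — a
documented limitation. Curves require more than 40 events (configurable);
below that the band is suppressed with its counts reported.

## Comparing scores and strata

* **Score versus score.** Two PRSs for the same trait are compared by a
  *paired* bootstrap: individuals are resampled with replacement and the
  same resample is evaluated under both scores, so cohort noise cancels
  and the comparison is like-for-like. The statistic is the difference of
  log-scale effects (log-OR/log-HR; raw beta for quantitative traits; the
  AUC difference when AUC is the metric — the alternative scale is a
  documented choice, not a claim about any particular published analysis).
  The 95% CI is the percentile interval of the bootstrap differences, and
  the two-tailed p-value is $2\min(\Pr(d\le 0), \Pr(d\ge 0))$ clipped
  below at $2/(B+1)$. 5000 resamples is the release-grade default; the
  identity comparison short-circuits to difference 0, $p = 1$.
* **Ancestry transferability.** For each trait the relative change of the
  log-scale effect in a target ancestry versus the reference (European by
  default), $(\beta_t - \beta_r)/\beta_r$, with a delta-method CI treating
  strata as independent; the cross-trait average is an
  inverse-variance-weighted fixed-effect mean. The change is undefined
  (and flagged) when the reference effect is not positive.
* **Age windows.** PRS hazard ratios within age-at-assessment bands (e.g.
  40–49 vs 60–69) over a 10-year incident horizon: prevalent cases are
  excluded, later events censored at the horizon, and the difference of
  log-HRs tested with independent-strata SEs.
* **Sex strata.** Effects within females and males (age adjustment only;
  sex is constant within a stratum) and a two-tailed z-test on the
  difference, starred at 0.05/0.01/0.001 in the summary tables. Strata are
  disjoint individuals, so independence is exact for sex.

## Carrier equivalence

Rare pathogenic-variant carriers (an input flag; classification is
upstream) are compared with the upper tail of the PRS distribution: the
carrier Kaplan–Meier risk at an anchor age (70 by default) is matched by
searching over top fractions $q$ of the score distribution for the band
whose risk at the anchor age is closest to the carrier risk. Because the
realized band risk is a noisy step function of $q$, the search evaluates
every fraction on a 0.5-percentile grid (configurable) and takes the
nearest, smallest $q$ on ties; the matching criterion is deliberately a
nearest-on-grid rule, not a root of a smooth function. Case-count ratios
between the matched band and carriers are reported at age cutoffs (<50,
<60, <70 by default), with band–carrier overlap counted in both groups and
reported against its expectation under independence. Within carriers,
curves stratified by full-cohort PRS bands show how the score modulates
carrier risk. Generic row filters (e.g. a statin-free restriction) can be
applied to any of these analyses as configured subgroup selections.

## Multivariate properties and mortality

Pairwise Pearson correlations between scores are computed
pairwise-complete, mirrored so the stored matrix is exactly symmetric, and
ordered for display by complete-linkage hierarchical clustering on
Euclidean distances of the correlation rows (rows pre-sorted by name, so
the leaf order is permutation-invariant).

All-cause mortality is modelled by forward-stepwise Cox selection over
candidate PRSs with Wald entry/removal thresholds (default
`entry_p = removal_p = 0.001`; strict because tens of candidate scores are
screened — the value is configurable and recorded in output). Two targets:

* **own** mortality — by default a left-truncated Cox model on the *age*
  timescale (entry at assessment, sex as covariate). The follow-up
  timescale with age as a linear covariate is available
  (`timescale = "followup"`), but when hazards rise steeply with age that
  model is misspecified across entry ages and attenuates the log-HR by
  roughly 10% in our generative checks; the age timescale also puts own
  and parental hazards on the same axis, which is what makes the 2:1
  comparison below like-for-like.
* **parental** mortality — one observation per parent (maternal and
  paternal records separate), time is the parent's age at death or last
  observation, adjusted for the participant's age at assessment and the
  parent's sex, with the *offspring's* score as predictor.
  Within-family correlation between the two parents of one participant is
  ignored in the SEs — a documented limitation.

Model quality is summarised by Harrell's C (usable-pair concordance, ties
0.5) for the full versus covariate-only model, the difference with a
paired-bootstrap CI, and Royston and Sauerbrei's $R^2_D$: the prognostic
index is replaced by its Blom normal scores scaled by
$\kappa = \sqrt{8/\pi}$, the Cox coefficient of that regressor is $D$, and
$R^2_D = (D^2/\kappa^2)/(D^2/\kappa^2 + \pi^2/6)$. This $D$-based variant
is the documented choice among the several "explained variation" measures
in the literature.

Because a parent shares half their additive genetic material with their
child, the offspring's score is, under a purely additive model, correlated
$\rho = 0.5$ with the parent's latent score; regressing *parental*
survival on the *offspring* score therefore recovers about half the
log-HR of the own-survival model, a 2:1 ratio. `parent_offspring_ratio()`
reports this ratio with a delta-method CI, and the synthetic generator
reproduces the mechanism exactly (parent latent score
$= \rho\,x + \sqrt{1-\rho^2}\,\varepsilon$, each person's hazard driven by
their *own* score). The residual parental term
$\sqrt{1-\rho^2}\,\varepsilon$ acts as a mild unobserved frailty and
attenuates the marginal parental slope by a few percent, so simulated
ratios sit slightly above 2 on average.

## The synthetic cohort generator

The generator emulates the statistical structure the evaluations assume:

* ancestry-stratified groups (default sizes 10000 EUR, 1000 SAS, 1000
  AFR, 300 EAS — proportional to a realistic biobank testing subgroup with
  deliberately boosted non-European representation) with standard-normal
  latent scores, configurable cross-score correlation and per-ancestry
  mean shift and SD scale on the raw (stored) scale;
* disease onset on the age axis from a proportional-hazards model with a
  piecewise-constant baseline (a coronary-disease-like default), per-SD
  log-HR, a sex effect, an optional linear age interaction on the
  log-hazard (so age-window analyses have a controllable truth), and rare
  carriers (default frequency 0.35%, hazard ratio 3) assigned
  independently of the score, as expected for common-variant scores versus
  rare variants;
* assessment ages Uniform(40, 69), ~15 years of administrative follow-up,
  and all-cause mortality (log-HR 0.2 per SD by default) driving both the
  death ages and censoring;
* parental lifespans via the $\rho = 0.5$ latent-score mechanism above,
  with parents about 28 years older than their child at observation;
* quantitative traits linear in the score with Gaussian noise and a sex
  mean shift, and a statin-like treatment flag generated from a noisy risk
  proxy so subgroup filters can be exercised under realistic confounding.

Event ages are drawn by inverse-transform sampling on the piecewise
cumulative hazard (with 1-year sub-bins when the age interaction is
active), and `expected_cumulative_risk()` provides the matching closed
form $1 - E[\exp(-e^{\beta x}\Lambda_0(a))]$ by quadrature over the
(optionally band-truncated) normal score distribution — the analytic
oracle used by the incidence and carrier tests. All randomness flows from
one root seed through named sub-streams, so adding a trait never perturbs
another trait's draws and the same seed reproduces output bit for bit.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: genotypes and linkage disequilibrium,
healthy-volunteer selection, phenotype misclassification and
under-reporting, secular changes in baseline hazards, non-proportional
hazards beyond the linear age interaction, and within-family environment
shared between parents and children.

## Numerical and design choices

* Standardisation uses the population-SD map (reference SD exactly 1).
* Cox ties: Breslow, switchable; KM intervals: complementary log-log.
* Gating is asymmetric by design: metrics need *at least* 100 cases,
  curves *more than* 40 events; both thresholds configurable.
* Percentile ranks use the "$\le$" empirical CDF with stable-id
  tie-breaks; bands are half-open `(low, high]` in percent.
* Missing data: complete-case per analysis, dropped counts always
  reported; cases lacking a diagnosis age are rejected, not imputed;
  individuals with missing sex are excluded from sex-adjusted models and
  counted.
* The bootstrap comparison seed, the stepwise thresholds and the
  incidence mode are recorded in every result; reports with the same
  inputs and seed are byte-identical apart from a timestamp.
* Test problem sizes: the micro-oracles run on 3–6 subjects against
  enumerated or grid-searched likelihoods frozen before implementation;
  parameter-recovery and calibration checks use simulated cohorts of
  15000–100000 individuals with 50–200 replicates where replication is
  needed — sizes chosen so Monte-Carlo error is small against the
  tolerances being asserted.

## Limitations

Kaplan–Meier band risks ignore competing mortality; the pipeline evaluates
predictive association, not calibration or absolute-risk modelling beyond
observed follow-up; no multi-PRS disease models are fitted (single score
plus covariates, except the mortality module); and the synthetic cohort,
however structured, is a statistical stand-in — conclusions about any real
biobank require the real data.
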