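---
title: "Identifying positive deviants in jurisdiction health-outcome panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying positive deviants in jurisdiction health-outcome panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posdev)
```

## The problem and the model

Local health departments (LHDs) operate under very different conditions:
county population, poverty, demographic composition, provider supply and
budget are largely outside their control. Comparing raw maternal-and-child
health (MCH) outcome rates across counties therefore mostly ranks counties
by their circumstances. The positive-deviance idea is to rank jurisdictions
by how much *better than expected* their outcomes are, where "expected" is a
regression prediction given context — and then to study the exceptional ones
to learn what they do differently.

`posdev` implements this as a three-step procedure, run separately within
each state, for each outcome, and for each year (a *cell*):

1. **Context model.** Regress the outcome on context variables Z only:
   $Y = \alpha + \beta_1 Z + e$.
2. **Full model.** Add mechanism variables X (factors under some LHD
   control — service-delivery arrangements, a clinician executive, a latent
   service-breadth score): $Y = \alpha + \beta_1 Z + \beta_2 X + e$.
3. **Model comparison.** A likelihood-ratio test (LRT) of the nested pair
   asks whether the mechanisms improve fit. Scoring nonetheless always uses
   the **full-model** residuals by default, so every cell is scored on the
   same model form; the LRT is reported, not gating. (The `residual_source`
   argument restores context-only scoring, which is also what the
   parsimonious sensitivity variant uses.)

A jurisdiction is a *candidate* positive deviant in a cell when its
**externally studentized residual** is strictly below −1 on a
lower-is-better outcome. Candidates are consolidated: only jurisdictions
flagged in **at least two (outcome, year) cells** — two outcomes in one
year, or one outcome in both years — enter the final positive-deviant set.

## Why externally studentized residuals

Raw residuals are not comparable across units or cells: their variance is
$\sigma^2(1-h_{ii})$, and the error variance differs by cell. The
externally studentized residual

$$t_i = \frac{e_i}{s_{(i)}\sqrt{1-h_{ii}}}, \qquad
s_{(i)}^2 = \frac{(n-p)s^2 - e_i^2/(1-h_{ii})}{n-p-1}$$

uses the leave-one-out variance estimate $s_{(i)}^2$ (computed by the
closed-form downdate, never by refitting), so unit $i$ does not inflate the
yardstick it is measured against. Under a correct Gaussian model $t_i$
follows a Student-t distribution with $n-p-1$ degrees of freedom, which
makes the fixed −1 threshold mean the same thing in a 35-county state as in
a 67-county one. Internal studentization would bound the residuals and
blunt outlier detection, which is why the external form is the default.

The threshold is deliberately inclusive: the lower tail of Student-t at −1
is about 0.16, so roughly one unit in six is flagged per cell *by chance*.
A stricter cutoff of −2 leaves too few candidates in small states to be
useful across community types. Specificity comes from **consolidation**,
not from the threshold: chance flags rarely recur, so requiring two cells
suppresses most of them, while jurisdictions that are genuinely better than
expected tend to be flagged repeatedly. The `analysis/05` driver and the
acceptance script quantify both sides of this trade-off on synthetic
panels. One consequence is worth stating plainly: with eight cells per
jurisdiction and a 16% chance rate, a jurisdiction that is truly
exceptional in only a *single* cell still frequently picks up one chance
flag elsewhere and enters the set — the two-cell rule filters one-off
deviants only partially (roughly half at the default configuration). This
is intrinsic to the threshold/consolidation design, not an implementation
artifact, and matches the inclusive behaviour the procedure shows on real
panels.

## Regression machinery and numerical choices

All fits go through `fit_ols()`, a minimum-norm least-squares solver built
on the singular value decomposition:

- **Rank deficiency** is expected, not exceptional: the covariate
  sensitivity analysis deliberately drops members of collinear pairs, and a
  duplicated or collinear column must not crash the run. The SVD solution
  uses singular values above `1e-10` times the largest; the effective rank
  is reported as $p$ and used in every degrees-of-freedom computation, so
  LRT df counts "estimable columns only" and a duplicated column adds
  df = 0 (statistic 0, p = 1).
- The log-likelihood is the Gaussian maximum
  $-\tfrac n2(\ln 2\pi + \ln\widehat{\sigma}^2_{ML} + 1)$ with
  $\widehat{\sigma}^2_{ML} = RSS/n$ — maximum likelihood, not REML, because
  the chi-square LRT reference requires it. A perfect fit (RSS = 0) yields
  an infinite-likelihood sentinel; an LRT against it reports p = 0 with a
  degeneracy flag.
- Leverage $h_{ii}=1$ makes a residual self-determined; such units get an
  `NA` score and are routed to the influence report instead.
- The chi-square LRT reference is **asymptotic**. In Gaussian linear models
  the exact null law of $n\ln(RSS_r/RSS_f)$ is an increasing function of an
  F statistic, and at the panel sizes used here ($n$ = 35–67, full models
  of 9–15 columns) the test rejects at nominal 5% closer to 7–10%. This is
  a known finite-sample property, documented here because the package
  reports LRT p-values without correction by default; the
  `correction = "bartlett"` option of `likelihood_ratio_test()` applies
  Box's multiplier scaling for users who want closer calibration. The
  identification itself is unaffected, since the LRT never gates the
  scoring model.
- **Influence rule.** An "influential leverage point" must be influential
  *and* a leverage point: flagged iff $h_{ii} > 2p/n$ **and** Cook's
  $D_i > 4/n$ (both standard cutoffs; both exposed as arguments). Each cell
  is refitted without its flagged units, and a jurisdiction's flag is
  recorded *robust* when it agrees between the two fits. The contract is
  exactly that agreement — removing units necessarily changes the fit, so
  robustness is defined on flags, not on residual values.
- All iteration orders are lexicographic and cell rows are sorted by
  jurisdiction id before fitting, so results are invariant to input row
  order and repeated runs are byte-identical. Identification involves no
  randomness at all.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | −1 | studentized-residual cutoff, strict `<`; −2 available but very restrictive |
| `min_cells` | 2 | flagged (outcome, year) cells required for consolidation |
| `residual_source` | `"step2"` | score on full-model residuals; `"step1"` for context-only |
| `correlation_cutoff` | 0.8 | within-state absolute correlation defining a collinear pair |
| `hat_multiplier` | 2 | leverage cutoff $h_{ii} > 2p/n$ |
| `cooks_threshold` | $4/n$ | Cook's distance cutoff |
| `pooled_years` | `FALSE` | fit each year separately (default) or pool years per state-outcome |

Per-year fitting is the default because outcomes are scored against peers
*in the same year*; pooling is provided because a single per-state-outcome
model is sometimes preferred for reporting, and context variables change
slowly enough that the pooled fit is meaningful.

## What the synthetic generator emulates — and what it does not

`default_study_config()` produces a panel with the study's shape: three
states of 35, 67 and 48 single-county jurisdictions, years 2009–2010,
giving 150 jurisdictions and 300 rows. Per jurisdiction it draws ten
context variables (log-normal expenditure, population and Medicaid-birth
counts for heavy-tailed spending spreads; normal index/percentage variables
clamped to their valid ranges; a 3-level community type at 52/23/25%
metropolitan/micropolitan/rural), with a Gaussian copula imposing pairwise
correlation 0.3 and one deliberately collinear pair at 0.85
(social disadvantage ~ child poverty) to exercise the sensitivity analysis.
Mechanisms are two Bernoulli indicators and a standard-normal latent score.
Outcomes follow the linear model exactly, with Gaussian noise independent
across all (jurisdiction, outcome, year) cells and intercepts placed so the
rates sit at realistic levels (teen births ~30, late prenatal care ~18,
infant mortality ~7, low birth weight ~8%). Effect sizes were chosen once
to spread context-model $R^2$ over roughly 0.15–0.7 across outcomes, the
range a practitioner would consider plausible for county panels; they are
not calibrated to any real dataset.

Positive deviants are planted as additive $-2.5\sigma$ mean shifts — the
simplest mechanism consistent with "better than the model predicts" — in
two cells for ~10% of jurisdictions and one cell for ~5%, with labels
returned as ground truth. Context is held fixed across the two years
(county attributes move slowly); a master seed drives deterministic
per-state substreams, so adding a state never perturbs another state's
draws.

The generator does **not** attempt spatial autocorrelation between
neighbouring counties, within-jurisdiction outcome correlation across years
or outcomes, non-linear context effects, or measurement error in the
covariates. Consequently, passing tests demonstrate that the machinery is
correct and that the procedure behaves as designed *when its assumptions
hold*; they say nothing about model misspecification on real panels, where
persistent jurisdiction-level shocks would make flags correlate across
cells and change the consolidation arithmetic.

## Validation strategy and problem sizes

The test suite checks every numerical component against an independent
route: studentized residuals and Cook's distances against physical
leave-one-out refits, coefficients/leverage/likelihood against a
pseudo-inverse oracle, LRT p-values against quadrature of the chi-square
density, and the whole pipeline against planted ground truth. Distributional
properties use 200–2,000 replicates of panels with 35–67 units (null LRT
calibration at n = 60 with 3 added columns; pooled residual tails over 500
study-shaped replicates; coefficient coverage over 500 replicates of the
largest state; planted-deviant recovery over 200 full-pipeline replicates)
— sizes chosen so each property estimate has a Monte-Carlo error well below
the tolerance it is tested at. `scripts/acceptance.R` recomputes the same
quantities from scratch for any seed.

## Known limitations

- Candidate identification does no multiple-testing correction across the
  24 cells; this is by design (the threshold is a screening device), but it
  is why single-cell candidates must not be over-interpreted.
- The uncorrected chi-square LRT is anti-conservative at these panel sizes
  (above).
- The two-cell consolidation rule only partially filters one-off deviants
  (above); stricter filtering requires either a lower threshold or a larger
  `min_cells`, both of which cost sensitivity.
- Rates are consumed as given; the package does not reconstruct them from
  numerator/denominator counts, impute missing cells, or model negative
  deviance ("worse than expected"), and all models are within-state —
  cross-state pooling would conflate state-level measurement differences
  with performance.
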