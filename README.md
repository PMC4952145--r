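# posdev — positive-deviance identification for jurisdiction health-outcome panels

Public-health jurisdictions (for example the county areas served by local
health departments) differ enormously in circumstances they cannot change:
population, poverty, demographic composition, provider supply, budget.
Comparing raw maternal-and-child-health outcome rates therefore mostly
ranks counties by circumstance. `posdev` instead identifies **positive
deviants** — jurisdictions whose outcomes are substantially *better than a
regression model predicts given their context* — so that their practices
can be studied and spread. It is aimed at public-health services
researchers and analysts with a jurisdiction-year panel of outcomes,
context variables, and "mechanism" variables under agency control.

## The method

Within each state, for each lower-is-better outcome `Y` and each year:

1. **Context model:** `Y = α + β₁Z + e` (Z = context).
2. **Full model:** `Y = α + β₁Z + β₂X + e` (X = mechanisms).
3. **Likelihood-ratio test** of the nested pair, `2(ℓ_full − ℓ_reduced)`
   against χ² with df = added rank. Scoring always uses the full model's
   residuals by default; the LRT is reported, not gating.

A jurisdiction is a candidate positive deviant in a cell when its
**externally studentized residual**
`t_i = e_i / (s₍ᵢ₎ √(1 − h_ii))` is strictly below **−1**
(t-distributed with `n − p − 1` df under a correct model, so the threshold
is comparable across states of different sizes). Candidates flagged in
**≥ 2 (outcome, year) cells** — two outcomes in one year, or one outcome in
both years — form the consolidated positive-deviant set. Influence
diagnostics (leverage `h_ii > 2p/n` **and** Cook's `D > 4/n`) drive a
leverage-sensitivity rerun per cell, and collinear-covariate and
parsimonious-model variants quantify the stability of the flagged set.

Because no real panel with these variables is publicly deposited, the
package ships a synthetic generator (`default_study_config()`,
`generate_panel()`) that reproduces the analysis' assumed structure — three
states of 35/67/48 single-county jurisdictions over two years, correlated
context (including one deliberately collinear pair), and planted deviants
with known labels — so the whole pipeline is testable end to end.

## Worked example

```r
library(posdev)

sim   <- generate_panel(default_study_config(seed = 2016L))
res   <- run_all_cells(sim$panel, threshold = -1)
print(res[[1]])
#> Cell (FL, infant_mortality_rate, 2009): n = 67, R^2 0.27 -> 0.38, LRT p = 0.010, 10 flagged (t < -1)
#>   flagged: FL-004, FL-007, FL-030, FL-034, FL-041, FL-047, FL-052, FL-053, FL-056, FL-064

pd <- consolidate(build_pd_matrix(res), min_cells = 2)
length(pd$members)
#> [1] 53

head(model_summary_table(res)[, c("state","outcome","year",
                                  "r2_step1","r2_step2","lrt_p_display")], 4)
#>  state                 outcome year r2_step1 r2_step2 lrt_p_display
#>     FL   infant_mortality_rate 2009    0.266    0.381         0.010
#>     FL   infant_mortality_rate 2010    0.124    0.296         0.002
#>     FL late_prenatal_care_rate 2009    0.400    0.444         0.162
#>     FL late_prenatal_care_rate 2010    0.435    0.544         0.003
```

Reading this: in the Florida infant-mortality cell for 2009, context alone
explains 27% of outcome variance and adding mechanisms raises it to 38%
(LRT p = 0.010); ten counties beat their model prediction by more than one
studentized-residual unit. After consolidation, 53 of the 150
jurisdictions are positive deviants in at least two (outcome, year) cells.
Since this panel is synthetic, the planted labels in `sim$truth` let you
check recovery directly.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on a fresh synthetic
panel and write all tables under `results/`:

| script | what it does |
|---|---|
| `analysis/01_simulate.R` | generate the panel + ground truth |
| `analysis/02_identify.R` | three-step identification, flag matrix, consolidated set |
| `analysis/03_sensitivity.R` | leverage-point and collinear-covariate stability |
| `analysis/04_report.R` | model-summary and PD vs non-PD expenditure tables |
| `analysis/05_operating_characteristics.R` | recovery/filtering rates over replicates |

`run_pipeline()` performs the same end-to-end run (simulate → validate →
identify → consolidate → sensitivity → report) from a single config, with
byte-identical outputs on repeated runs.

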