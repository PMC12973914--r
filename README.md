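# isfmtrial

Analysis toolkit for multi-season factorial fertility trials of the kind
used to evaluate **integrated soil fertility management (ISFM)** — the
combined use of mineral fertilizer, biochar, vermicompost and lime on
degraded, acidic cropland. The package covers the complete chain from raw
plot records to an economic recommendation for a two-season 3 × 3 × 3
N/P₂O₅ × biochar × vermicompost maize trial laid out as a randomized
complete block design (RCBD) with three replicates:

- **Agronomic conversions** — net-plot mass to kg ha⁻¹
  (`plot_to_hectare()`), grain-moisture standardization to 12.5%
  (`adjust_moisture()`, GY × (100 − MC)/(100 − 12.5)), the 10% farmer-level
  yield deduction (`farmer_adjust()`), amendment conversion yields and
  per-tonne production costs (`conversion_yield()`,
  `amendment_unit_cost()`), vermicompost nitrogen equivalence
  (`vc_nitrogen_equivalence()`, NEvc = 10 × TN) and the Kamprath-style lime
  requirement from exchangeable acidity (`lime_requirement()`,
  LR = lf × Exc.Ac with lf = 1.5).
- **Inference** — combined-over-years fixed-effects ANOVA
  (`fit_trial_anova()`) with the classical source decomposition (Block,
  the three treatment factors, Year, and all their interactions, tested
  against the pooled residual; 106 error df on the full 27 × 3 × 2 layout),
  LSD mean separation (`lsd_value()`,
  t₁₋α/2 √(2 MSE/n)), compact letter displays (`compact_letters()`),
  Pearson trait correlations with significance classes
  (`trait_correlations()`), and the Shapiro–Wilk / variance-ratio
  pre-analysis screens.
- **Partial-budget economics** (CIMMYT style) — gross and net benefit,
  dominance analysis (`dominance_analysis()`), stepwise marginal rate of
  return along the net-benefit frontier (`marginal_rate_of_return()`,
  MRR = ΔNB/ΔTVC × 100), and a recommendation against a minimum acceptable
  rate of return (`recommend_treatment()`, MARR = 100% by default).
- **A calibrated synthetic-trial generator** (`simulate_trial()`,
  `calibrated_spec()`) that reproduces the published treatment means and
  residual CVs of the reference trial, so the whole pipeline is testable
  although the raw plot data are not public.
- **Bundled reference tables** (`reference_*()`) — the published treatment
  codebook, cell means, prices, production-cost items and partial budget of
  the reference trial, transcribed for use as inputs and test anchors.

Everything takes and returns tibbles, fitted objects have `tidy()` /
`glance()` methods, and result types have `autoplot()` methods.

## Worked example

Simulate a trial under the published conditions, run the ANOVA with mean
separation, then the partial budget from the published cost/benefit table:

```r
library(isfmtrial)

rec <- simulate_trial(calibrated_specs(c("GY", "BY")), seed = 2024)
fit <- fit_trial_anova(rec, "GY")
glance(fit)
#>   trait grand_mean    cv r.squared   mse df_error  nobs
#> 1 GY          9.24  4.33     0.969 0.160      106   162
head(tidy(fit), 6)
#>   term        df   sumsq meansq statistic  p.value sig
#> 1 Block        2   0.304  0.152     0.951 3.90e- 1 ns
#> 2 N/P2O5       2 199.    99.4     622.    2.75e-59 **
#> 3 BC           2 169.    84.4     528.    7.68e-56 **
#> 4 VC           2  51.4   25.7     161.    7.83e-33 **
#> 5 Year         1   0.925  0.925     5.79  1.79e- 2 *
#> 6 N/P2O5:BC    4  59.4   14.9      92.9   9.39e-34 **
```

The grand mean (9.24 t ha⁻¹), residual CV (4.3%) and error df (106) match
the reference trial's published grain-yield analysis, and the three
amendment factors are, as published, highly significant. The treatment
means carry LSD letters (`means_table(fit)`; LSD(0.05) = 0.458 t ha⁻¹ at 6
observations per mean), with the 120/69 + 4 t biochar + 5.02 t
vermicompost combination in the top letter group.

The economics start from published net benefit (NB) and total variable
cost (TVC):

```r
bud <- reference_budget() |>
  dominance_analysis() |>
  marginal_rate_of_return()
bud[!bud$dominated, c("treatment", "tvc", "nb", "mrr")]
#>   treatment    tvc      nb    mrr
#> 1 T1         22694  128546     NA
#> 2 T10        44094  216834 412.56
#> 3 T13        69950  254047 143.93
#> 4 T14        93481  289124 149.07
recommend_treatment(bud)$recommended
#> [1] "T14"
```

Only T1 (limed control), T10 (4 t biochar), T13 (half N/P + biochar) and
T14 (half N/P + biochar + vermicompost) sit on the net-benefit frontier;
every step beyond T1 returns more than the 100% MARR, and T14 — the
highest net benefit, 289,124 ETB ha⁻¹ at an MRR of 149.07% — is the
recommended treatment. `autoplot(bud)` draws the net-benefit curve.

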