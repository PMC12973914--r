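---
title: "Methods: factorial ISFM trial analysis and partial-budget economics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factorial ISFM trial analysis and partial-budget economics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isfmtrial)
```

## The trial and its statistical model

The package is built around one experimental archetype: a two-season,
three-replicate randomized complete block design whose 27 treatments are
the full cross of three nitrogen/phosphorus levels (0/0, 120/69,
240/138 kg N/P₂O₅ ha⁻¹, applied jointly and never mixed across pairs),
three maize-cob biochar rates (0, 4, 8 t ha⁻¹) and three vermicompost
rates (0, 5.02, 10.04 t ha⁻¹), on a very strongly acidic soil that
additionally receives a uniform lime dressing of 0.63 t CaCO₃ ha⁻¹ (lime
is a blanket treatment, not a design factor). `treatment_codebook()` is
the authoritative map from treatment ids T1–T27 to factor levels.

The combined-over-years analysis (`fit_trial_anova()`) is the classical
fixed-effects decomposition

$$y_{ijklr} = \mu + \beta_r + \alpha_i + \gamma_j + \delta_k + \tau_l
  + (\text{all interactions among } \alpha,\gamma,\delta,\tau)
  + \varepsilon_{ijklr},$$

with block $\beta_r$ ($r = 1..3$), N/P₂O₅ $\alpha_i$, biochar $\gamma_j$,
vermicompost $\delta_k$, year $\tau_l$ and i.i.d. Gaussian plot error.
Three structural choices deserve comment:

* **Block is a single 3-level factor crossed with year** (2 df), not
  nested within year (4 df). With blocks nested the combined layout would
  leave 104 error df; crossed, the full 27 × 3 × 2 table has 161 total df,
  55 model df and **106 error df**, which is the convention this package
  follows for combined analyses of this design.
* **Year is a fixed effect tested against the pooled residual.** A
  random-year (mixed) analysis would test treatment terms against
  treatment × year mean squares; the combined tables this package mirrors
  use the pooled-residual convention, and we reproduce it. Users who need
  a mixed analysis should fit one directly (e.g. `lme4`); it is outside
  this package's scope.
* **Sums of squares are sequential.** On the balanced complete layout the
  factors are mutually orthogonal, so sequential, marginal and type-III
  decompositions coincide; on unbalanced input the fit degrades to
  sequential SS and says so with a warning rather than silently changing
  meaning.

The pre-analysis screens mirror standard practice: Shapiro–Wilk on the
trait (`normality_screen()`, pass when p > 0.05) and a two-sided variance
ratio F-test between the two years' residuals (`variance_homogeneity()`).
A failed normality screen is reported with a suggestion to apply an
explicit log or square-root transform; the package never transforms data
silently, because a silently transformed mean table is a trap for the
reader.

### Mean separation and letters

`lsd_value()` implements the least significant difference
$t_{1-\alpha/2,\,\nu}\sqrt{2\,\mathrm{MSE}/n}$ with $\nu$ the error df and
$n$ the observations per compared mean — **6** for combined-over-years
three-way treatment means (3 blocks × 2 years), 3 within a single year,
54 for main-effect means. `means_table()` derives $n$ from the actual
group sizes rather than trusting a constant.

Because a single LSD threshold makes "not significantly different" an
interval relation on the sorted means, the compact letter display
(`compact_letters()`) does not need the general insert-and-absorb
machinery: the letter groups are exactly the maximal runs of sorted means
whose extremes differ by at most the LSD, lettered `a` from the largest
mean downward. Ties are broken by descending mean and then label order, so
the output is deterministic. The tests verify the shared-letter ⇔
|Δmean| ≤ LSD equivalence exhaustively on hundreds of random mean sets.

### Correlations

`trait_correlations()` reports Pearson r per trait pair with the two-sided
t-test classing used in agronomic tables: `**` for p < 0.01, `*` for
p < 0.05, `ns` otherwise. Constant traits give an undefined r and are
flagged, not dropped.

## The synthetic generator and its calibration

The raw plot records of the reference trial are not public, so the
package ships a generator (`simulate_trial()`) for the linear model above.
An `effect_spec()` carries the grand mean, zero-sum effect vectors for
year, block and the three factors, optional zero-sum interaction arrays
(any subset, including with year) and the plot-error SD; the zero-sum
constraint keeps the parameterization identifiable so recovered ANOVA
effects are comparable to the injected ones.

`calibrated_spec(trait)` anchors the generator to the published summaries
(`reference_cell_means()`, `reference_trait_summary()`):

* the published 27-cell combined-over-years mean table is decomposed
  exactly into main effects, the three two-way interactions and the
  three-way interaction, so the generator's expected cell means equal the
  published means (up to the constant offset between the published pooled
  mean, which anchors the spec, and the average of the published cells —
  at most a few parts per thousand, caused by rounding in the source
  tables);
* the error SD is `cv/100 × grand mean` from the published residual CV,
  e.g. grain yield 0.398 t ha⁻¹ from CV 4.296% around 9.258 t ha⁻¹;
* year effects use the published year means where those exist (grain and
  biological yield); for the other traits per-year combined tables were
  not published and the year effect defaults to zero;
* block effects default to zero — the published block mean squares are
  non-significant throughout — and remain a free knob;
* harvest grain moisture is drawn uniformly from 14–25%, the plausible
  field range for rain-fed maize at this site, and the raw net-plot masses
  are derived by inverting the moisture and area conversions so the
  loader → conversion → analysis chain can be tested end to end.

What the generator deliberately does **not** emulate: spatial
autocorrelation within blocks, missing plots, heavier-tailed or
variance-heterogeneous errors, weather covariates, and any year-varying
error SD (the source reports a single pooled CV per trait). Passing tests
therefore demonstrate that the *pipeline* is correct under the stated
model, not that real fields obey it; the pre-analysis screens are the
user's first line of defence when they do not.

The generator/ANOVA loop is calibrated in the acceptance suite under
fixed seeds: with all effects zero, each of the 16 F-tests rejects at
α = 0.05 in 5% ± 2% of 1000 simulated trials; with main effects spanning
3 error SDs, power at α = 0.01 exceeds 95% over 200 trials. These problem
sizes give Monte-Carlo standard errors of about 0.7 and 1.5 percentage
points respectively, small enough to detect a miscalibrated test while
keeping the default suite around half a minute.

## Agronomic conversions

All formulas are single-purpose and fully vectorized; computation is at
full precision, with rounding to printed conventions confined to the
reporting layer (`format_budget()`).

* `plot_to_hectare()`: mass / net area × 10 000. The net plot defaults to
  1.65 m × 2.5 m = **4.125 m²** — the value inside the yield-conversion
  formulas — although trial write-ups of this design sometimes quote a
  3.63 m² nominal net area; the area is a `trial_design()` parameter, so
  either convention is one argument away.
* `adjust_moisture()`: × (100 − MC)/(100 − 12.5); 12.5% is the maize
  marketing standard. Linear, hence commutes with the area scaling.
* `farmer_adjust()`: × (1 − 0.10) by default, the usual deduction for
  farmer-level realities when station results feed a budget.
* `vc_nitrogen_equivalence()`: 10 × TN(%), the 100 kg → 1 t scale-up.
  With the measured mean TN of 2.42% this gives 24.2 kg N t⁻¹ (narrative
  citations of ~23.9 correspond to TN ≈ 2.39%).
* `lime_requirement()`: 25% of lf × Exc.Ac with lf = 1.5. The conversion
  from cmol_c kg⁻¹ to t CaCO₃ ha⁻¹ is, in the field recommendation this
  reproduces, a *numeric equivalence* — the number is simply re-read in
  t ha⁻¹ (0.25 × 1.5 × 1.68 = 0.63). That is physically informal, so the
  function announces the convention and offers `physical = TRUE`, which
  converts through soil mass per hectare (incorporation depth × bulk
  density) and the 50 g mol_c⁻¹ CaCO₃ equivalent weight. For this site
  (20 cm, 1.41 g cm⁻³) the physical full rate is ≈ 3.6 t ha⁻¹ against the
  conventional 2.52 — users should know which one they are applying.
* `percent_increase()` defaults to the **treated-mean denominator**,
  (treated − reference)/treated × 100. The conventional reference-based
  form is available via `base = "reference"`; the treated-base form is
  the default because it is the convention under which the published
  percent effects of the reference trial (63.73%, 44.83%, 22.89%, 32.92%)
  are reproducible, and consistency with the reference figures matters
  more here than the more common convention.
* `amendment_unit_cost()` sums recorded item totals and divides by the
  application basis. Item totals are taken **as given** rather than
  recomputed from quantity × unit cost: recorded cost tables routinely
  embed lump sums and rounded billing, and silently "fixing" them would
  make the output irreconcilable with the source. The bundled biochar
  items sum to 41 279.60 ETB (printed as the rounded 41 280), giving
  5 159.95 ≈ 5 160 ETB t⁻¹ over the 8 t ha⁻¹ basis; the vermicompost
  items sum to 21 388.19 ETB, giving 2 130.30 ETB t⁻¹ over 10.04 t
  (the source prints 2 130.29, a truncation).

## Partial-budget economics

`dominance_analysis()` sorts by TVC and flags a treatment as dominated
when any cheaper-or-equal treatment has at least its net benefit; the
undominated set is the strictly increasing NB frontier. Exact (TVC, NB)
ties keep the first row by sort order undominated — an arbitrary but
deterministic rule.

`marginal_rate_of_return()` computes MRR = ΔNB/ΔTVC × 100 against a
reference row. The textbook phrase "immediate lower TVC" is ambiguous
when dominated rows sit between frontier points; reconciling the
published MRR column of the reference budget shows the reference actually
used is the **nearest undominated row with strictly lower TVC** — the
frontier step a farmer could actually take — and that verified rule is
the default, with `reference = "immediate"` available for the literal
reading. Zero-ΔTVC steps are undefined and flagged; zero-ΔNB steps are 0%.
MRR is scale-free: multiplying all costs and benefits by a constant
changes nothing, which the tests assert.

Against the published table, the computed MRR column agrees at printed
precision for 22 of 26 non-base rows. The four exceptions are slips in
the source, not in the rule: one row is printed rounded to whole percent
(computed 412.56, printed 413), three differ in a single digit (−88.62
printed −88.66; −414.93 printed −413.93; −2 488.56 printed −2 488.36),
and one reconciles only by mixing the NB difference against one reference
row with the TVC difference against another (computed −5 415.88, printed
−11 468.6). The tests pin the 22 agreements exactly
and document the four slips.

The published gross benefits are themselves not reproducible from the
published yields and any published price set (e.g. the recommended
treatment: 383 954.98 computed from mean prices against 376 565.94
printed), and printed NB ≠ printed GB − TVC; the source's intermediate
rounding/averaging order is unrecoverable. `build_budget()` therefore
supports both entry points — yields + prices (everything recomputed,
NB ≡ GB − TVC by construction) or a pre-computed NB/TVC table taken as
given — and the acceptance checks use whichever the claim being checked
was published under. The published price table also carries two internal
slips (the NPSB and straw mean prices are not the yearly means);
`check_price_table()` flags them instead of repairing them.

`recommend_treatment()` applies the MARR (default 100%): among
undominated treatments with MRR ≥ MARR, highest NB wins, ties to the
cheaper one; if nothing qualifies the base treatment is returned with a
warning rather than an invented recommendation.

## Numerical and interface choices

* Full precision everywhere internally; IEEE doubles round-trip through
  the CSV writers (`write_table()` uses readr's shortest-roundtrip
  rendering). Display rounding is half-up at printed precision and only
  in `format_budget()` / report rendering.
* The trait vocabulary is closed (DPM, PH, NLPP, EL, ENPP, GNPE, NRPE,
  TGW, BY, GY, plus MC and the derived plot masses); unknown columns pass
  through untouched and are excluded from built-in analyses, so user
  metadata survives the loader.
* The "quintal" in the bundled cost items is the local unit (≈ 38.86 kg
  of dry maize cob), not the 100 kg metric quintal; it is recorded as a
  unit label and never converted.
* Currency values are plain decimals with unit labels; no cross-currency
  arithmetic is attempted beyond recording the exchange rate.
* `report_trial()` stamps every output file with the package version and
  a caller-supplied run label, so a results directory is traceable.

## Known limitations

* No mixed-model/REML analysis, no multiple-testing correction beyond the
  LSD, no Tukey/Duncan alternatives — deliberately, to stay faithful to
  the analysis convention the package reproduces.
* The generator's Gaussian, homoscedastic, spatially independent errors
  are an idealization; see the calibration section for what passing tests
  do and do not establish.
* Published per-trait F and mean-square values, printed LSDs and the
  published correlation matrix cannot be verified without the raw data
  and are not asserted anywhere; the printed grain-yield LSD (0.1518) is
  not even consistent with the printed error mean square at any plausible
  per-mean replication, so the package's own LSDs will differ from
  printed ones even at identical MSE.
* Single reference archetype: the design constants default to this
  trial's geometry and levels. The loaders and ANOVA accept any complete
  two-factor-crossed-with-year RCBD of the same 3 × 3 × 3 shape;
  generalizing the factor structure is future work.
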