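# shrubmeta

Random-effects meta-analysis of multi-site shrubland manipulation
experiments — warming, increased precipitation, drought, and nitrogen
addition — for ecologists synthesising vegetation responses (aboveground
biomass, ANPP, cover, density, species richness, Shannon diversity, and
the shrub proportion of the community) across globally distributed field
sites.

## The model

Each study contributes one treatment–control contrast per vegetation
metric. The effect size is the natural-log response ratio with its
delta-method sampling variance from the arm summaries:

    RR = ln(X_t / X_c)
    VI = SD_t² / (n_t X_t²) + SD_c² / (n_c X_c²)

Within each metric × treatment stratum the RRs are pooled under the
random-effects model `y_i ~ N(μ, v_i + τ²)` with inverse-variance
weights `1/(v_i + τ²)`; τ² is estimated by REML (DerSimonian–Laird is
available as a cross-check), significance by a Wald-type z test, and
intervals both as Wald `μ ± 1.96·SE` and as bias-corrected bootstrap
percentile intervals over resampled studies. Results are reported on
the percentage scale `100·(e^RR − 1)`.

Publication bias is screened per stratum with Egger's regression
(standardised effect on precision); when the intercept is significant
the headline estimate switches to the PEESE correction — the intercept
of the `1/v_i`-weighted regression of effect on variance, i.e. the limit
of an infinitely precise study. Short-term (1–5 yr) and long-term
(> 5 yr) experiments are pooled separately and contrasted with a normal
z test on the difference.

To compare experiments of different intensity, percentage changes are
standardised to **sensitivities**: % per °C (warming), % per
g N m⁻² yr⁻¹ (nitrogen), % per 10 mm of precipitation change
(increased precipitation and drought). Sensitivities are regressed on
site climate — mean annual temperature and the aridity index (AI,
higher = more humid; linear or natural-log form) — in a mixed-effects
meta-regression, with the moderator chosen by the lowest ML AIC.

A synthetic-data module generates whole experiment networks with known
truth (per-site effects, heterogeneity, χ²-distributed sample SDs,
optional significance-based publication censoring), so every stage is
testable without field data.

## Worked example

Simulate a 30-site drought network with a true −14% biomass effect
(RR = −0.15) and moderate heterogeneity, then run the core analyses:

```r
library(shrubmeta)

cfg <- simulation_config(k_sites = 30, treatment = "drought",
                         metric = "AGB", true_beta0 = -0.15,
                         tau2 = 0.02, seed = 2024)
sim <- simulate_dataset(cfg)
es  <- compute_effect_sizes(aggregate_studyset(sim$studyset))

pool(es$rr, es$vi, method = "REML")
#> <pooled_result> k=30  mu=-0.1310 (SE 0.0369)  tau2=0.0245 [REML]
#>   percent: -12.28% [-18.39, -5.70]  z=-3.551 p=0.0003836

bias_workflow(es$rr, es$vi)
#> <bias_diagnostics> Egger intercept 0.851 (p=0.306); PEESE -0.1872; applied=FALSE
#>   headline: -12.28%

sensitivity_gradient_report(es)
#>   metric treatment  k moderator transform     slope        se         z
#> 1    AGB   drought 30 AI_linear    linear -1.777744 0.8556219 -2.077722
#>            p      aic       label
#> 1 0.03773497 139.0494 significant
```

The pooled drought response is −12.3% (95% CI −18.4 to −5.7,
p < 0.001), close to the simulated −14%; Egger's test finds no
asymmetry (p = 0.31), so the naive estimate stays the headline; and the
sensitivity of biomass to drought increases (becomes less negative)
toward more humid sites at −1.78% per 10 mm per AI unit (p = 0.038) —
the aridity dependence the generator was told to produce is recovered.
`run_pipeline()` chains all stages (read → aggregate → effect sizes →
pooling → bias → duration subgroups → moderator regressions) and writes
a JSON report plus CSV tables; `inst/scripts/shrubmeta.R` exposes
`simulate` / `run` / `fixtures` subcommands for shell use.

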