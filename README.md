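# quitcea

Cost-effectiveness modelling of a lung-cancer genetic test added to a usual
smoking-cessation program.

## The problem

Smoking-cessation programs (nicotine replacement therapy plus counselling)
are cheap and effective but suffer low 12-month quit rates and high
long-term relapse. Personalised genetic feedback on lung-cancer risk might
motivate more smokers to quit and stay quit — but the test adds $355.90 per
person. `quitcea` is for health economists and modellers who want to ask,
with a fully reproducible pipeline: *how much behaviour change must the
test produce to be worth paying for?*

The core is a two-strategy Markov cohort model: usual smoking cessation
(USC, quit rate 6%) versus USC plus genetic test (GT, quit rate 11%),
following a cohort of heavy smokers aged 50 for 35 annual cycles through
five health states — no lung cancer (quit), no lung cancer (smoking), early
lung cancer, advanced lung cancer, death — with 5-year tunnel states for
time since cancer diagnosis. Costs and QALYs are discounted at 5% and
combined into

```
ICER = (C_GT − C_USC) / (E_GT − E_USC),    NMB = λ·E − C  at λ = $20,000/QALY
```

with one-way, threshold, break-even and scenario analyses and a
10,000-iteration probabilistic sensitivity analysis (beta for
probabilities, gamma for costs) with a cost-effectiveness acceptability
curve. The age-indexed epidemiology (background mortality, lung-cancer
incidence, smoker/ex-smoker relative risks, cancer survival) is generated
by an anchored synthetic module pinned exactly to published single-age
values, so the whole pipeline runs self-contained — see
`vignette("model-methods")` for what that does and does not reproduce.

## Worked example

```r
library(quitcea)
cfg <- ce_config()            # base case (Table-anchored defaults)

short_term(1000, cfg$strategies$usc, cfg$strategies$gt)
#> # A tibble: 1 × 8
#>   cohort_size cost_usc cost_gt quitters_usc quitters_gt delta_cost
#> 1        1000   802100 1158000           60         110     355900
#> # delta_quitters 50, cost_per_additional_quitter 7118
```

For every 1,000 smokers the genetic-test arm costs $355,900 more and yields
50 extra 12-month quitters: $7,118 per additional quitter.

```r
run_ce(cfg)
#> <ce_result> base case
#>   USC: $7648.01, 14.6733 QALYs | GT: $7924.49, 14.6878 QALYs
#>   delta: $276.48, 0.01451 QALYs (tradeoff)
#>   ICER: $19050 per QALY
#>   incremental NMB at WTP $20,000: $13.79
```

Over 35 years the test adds ≈$276 per person (the $355.90 program cost
minus averted cancer care) and ≈0.015 QALYs: about $19,000 per QALY under
the synthetic tables, just under the $20,000 willingness-to-pay. The
margin is thin, which is the substantive point — the result is volatile in
the quit and relapse rates:

```r
as.numeric(threshold_quit_rate(cfg))       # GT quit rate with equal net benefit
#> [1] 0.1081
as.numeric(breakeven_quit_rate(cfg))       # quit rate at which GT dominates
#> [1] 0.2841
glance(scenario(cfg, start_age = 60))$icer # older cohort: more favourable
#> [1] 11073.23
run_psa(cfg, n = 10000, seed = 1)
#> <psa_result> 10000 iterations (seed 1)
#>   mean ICER (ratio of means): $18833 per QALY
#>   95% CI (percentile, positive-effect draws): $2849 - $299970
#>   P(cost-effective at WTP $20,000): 49.8%
```

`autoplot()` draws the cost-effectiveness plane for a PSA and the
compartment trace for a cohort run; `plot_ceac()` and `plot_tornado()`
cover the acceptability curve and one-way sensitivities. `tidy()` and
`glance()` return tibbles for every result type. A thin command-line
wrapper ships in `inst/cli/quitcea.R`
(`Rscript quitcea.R run|short-term|owsa|threshold|psa|scenario|synth-epi`).

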