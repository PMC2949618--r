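---
title: "Model and methods: genetic testing within smoking cessation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: genetic testing within smoking cessation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decision problem

quitcea implements a two-strategy Markov cohort model for a question in
preventive health economics: if a lung-cancer susceptibility test (a SNP
panel plus clinical risk assessment) is added to a usual smoking-cessation
program — nicotine replacement therapy (NRT) with telephone counselling — how
much extra quitting or reduced relapse must the personalised risk feedback
produce for the addition to be worth paying for?

The comparison is incremental: usual smoking cessation (USC) versus the same
program plus the genetic test (GT). Per person, USC costs $802.10 (GP visit,
a 10-week step-down patch course, five counselling sessions, a booklet) and
GT adds $355.90 (two extra clinic visits, the $311 test, a results booklet),
for $1,158.00 total. The behavioural difference is carried by two parameters:
the 12-month continuous-abstinence quit rate (6% under USC, 11% under GT,
from trial evidence) and a multiplier on the shared annual relapse schedule.

## Model structure

A cohort of heavy smokers aged 50 is followed for 35 annual cycles through
five health states: no lung cancer (quit), no lung cancer (still smoking),
early-stage lung cancer (I/II), advanced-stage lung cancer (III/IV), and
death. Costs and quality-adjusted life-years (QALYs) are accumulated per
cycle and discounted at 5% a year; the payer perspective covers intervention
costs and lung-cancer care.

Two kinds of time-in-state memory are required, handled differently:

* **Cancer tunnels.** Each cancer state is a 5-year tunnel indexed by time
  since diagnosis, because both the annual cancer death probability and the
  first-year treatment cost depend on it. Survivors of year 5 move to a
  long-term "stable disease" compartment with ongoing care costs and
  background mortality only (the excess cancer hazard is set to zero beyond
  the published 5-year survival table — the tail rule).
* **Time since quitting.** Quitting happens once, at the start of the
  simulation, and relapsers never re-quit (the intervention is one-off).
  Years-since-quit therefore equals the cycle index for every occupant of
  the quit state, and no quit-time tunnel is needed. This indexes both the
  relapse schedule (10% in years 2–6, 4% after) and the ex-smoker relative
  risk of lung cancer.

That yields 15 compartments: the two no-cancer states, five tunnel steps per
stage, two stable compartments, and death.

### Event ordering and transition construction

The source evidence does not specify an intra-cycle competing-risk order, so
one is fixed and documented: background death first, then cancer events
(onset in the no-cancer states; cancer death, then early-to-advanced
progression in the tunnels), then relapse among the surviving quitters.
Transition rows are built from complements so each row sums to 1 exactly; a
row sum outside 1 ± 1e-9 raises an error rather than being renormalised
(a probability leak is a construction bug, not something to paper over).

Cancer onset in a cycle is background incidence at the current age times the
relevant relative risk — the current-smoker RR for smokers, the
years-since-quit-indexed ex-smoker RR for quitters — split 20% early / 80%
advanced stage at diagnosis.

### Rewards

State rewards (utilities 1 / 0.73 / 0.66 / 0 and cancer care costs) accrue
on the occupancy at the start of each cycle; first tunnel years carry the
stage-specific first-year treatment cost ($44,274 early, $27,057 advanced),
later cancer years the ongoing stable-disease cost ($7,115). Two costs are
transition-linked: progressive-disease care ($10,945) on the
early-to-advanced move, and terminal care ($9,961) on deaths attributable to
the cancer hazard in the cycle they occur. The one-off intervention cost is
charged at cycle 0, undiscounted (discounting it at t = 0 would be a no-op
anyway under the annual convention used). No half-cycle correction is
applied by default; a config flag enables it, and everything reported here
keeps it off.

Two parameters the evidence base leaves open are exposed in the config and
swept in sensitivity analysis rather than hidden: the annual
early-to-advanced progression probability (default 0.15) and the mapping of
the progressive-disease cost to the progression transition.

## Synthetic epidemiology tables

The age-indexed inputs (background mortality, lung-cancer incidence, smoker
and ex-smoker relative risks, cancer survival) come from national statistics
that are not published alongside the model, only example values are. The
`synthetic` generator therefore produces smooth parametric tables pinned
*exactly* to those printed anchors, so the pipeline is self-contained and
the anchors are reproduced to the last digit:

* Mortality: Gompertz-type, `q(a) = 0.00936 · exp(0.09 (a − 65))`. The
  anchor is the published annual death rate at 65; the slope 0.09/year is a
  standard adult Gompertz value.
* Incidence: exponential in age, `i(a) = 0.0018024 · exp(0.08 (a − 65))`;
  lung-cancer incidence roughly doubles every 8–9 years of age in this range.
* Current-smoker RR: 6.609 (heavy smokers vs the general population).
* Ex-smoker RR: exponential decay from 6.609 toward a floor of 1.5 (risk
  stays elevated indefinitely, consistent with cohort evidence out to 40+
  years since quitting), passing exactly through the published anchor RR of
  4.75 for the 50–55 age group, placed at 3 years since quitting — the
  midpoint of that group's first five quit years for a cohort quitting at 50.
* Cancer survival: the published all-stage curve (36% at 1 year, 12% at 5)
  with log-linear interpolation between, giving a constant conditional death
  probability of `1 − (0.12/0.36)^{1/4} ≈ 0.240` in years 2–5 after the
  0.64 first-year probability. Stage-specific curves apply a
  proportional-hazards factor 0.5 to the all-stage curve for early disease
  and define advanced survival as the residual, so the 20/80 stage mixture
  reproduces the published curve identically at every year.
* Sex: men carry a multiplier 1.2 and women 0.8 on the relative-risk excess
  (RR − 1), reflecting heavier smoking histories in men; background
  mortality and incidence are kept sex-neutral. This is deliberately
  minimal — it produces the right risk ordering without inventing sex-specific
  life tables.

What these tables do **not** emulate: cohort effects, the real age-shape of
the national tables (only their level at the anchor ages), smoker-specific
excess *non-cancer* mortality (off by default; the sources give no values
for it), and any calibration to registry data. Consequently the long-term
base-case results are reproduced in direction and order of magnitude, not
digit for digit: with these tables the base ICER is ≈$19,000 per QALY where
the original tables gave $27,572. Everything arithmetic — the short-term
cost-per-quitter panel, the intervention totals, the relapse compounding —
is exact, and the qualitative structure (scenario orderings, threshold
behaviour, dominance break-evens) is preserved and tested.

## Economic outputs

The incremental cost-effectiveness ratio is `ICER = (C_GT − C_USC) /
(E_GT − E_USC)` with per-person discounted totals; dominance is classified
before the ratio is reported (dominant / dominated / tradeoff / undefined at
zero incremental effect). Net monetary benefit `NMB = λ·E − C` at
willingness-to-pay λ = $20,000 per QALY drives every threshold search,
because for positive incremental effect `incremental NMB > 0 ⇔ ICER < λ`
exactly (fuzz-tested as an algebraic identity).

Threshold searches are bisections (tolerance 1e-6 dollars of NMB, max 200
iterations) on a monotone incremental-NMB or incremental-cost function,
cross-validated in the tests against exhaustive 1e-3 grid scans:

* `threshold_quit_rate()`: GT quit rate at which the two arms have equal net
  benefit.
* `threshold_relapse_reduction()`: relapse reduction (1 − multiplier) doing
  the same. Under the synthetic tables the base case is already below the
  WTP with the 11%/6% quit rates, so the search at those rates has no
  crossing and reports "always cost-effective in bracket"; with
  `equalize_quit = TRUE` the GT quit rate is set to the USC rate and the
  test's entire benefit must flow through relapse, which always produces a
  well-defined threshold.
* `breakeven_quit_rate()`: the quit rate at which averted cancer costs fully
  offset the extra $355.90, i.e. the GT arm becomes dominant. With the
  synthetic tables this lands near 28% (the original analysis reported 29%),
  and removing relapse drops it to ≈14% — the ordering that matters.

## Probabilistic sensitivity analysis

Uncertain parameters get beta distributions (probabilities, utilities) or
gamma distributions (costs), moment-matched from the published point
estimate and range, reading the range as a central 95% interval:
`sd = (high − low)/3.92`, then `α = m(m(1−m)/v − 1)` etc. for the beta and
`shape = m²/v`, `rate = m/v` for the gamma. The default uncertain set is
every parameter with a published one-way range (quit rates 7–22% and 3–12%,
stage split 13–23%, utilities 0.69–0.83 and 0.30–0.76) plus the five cancer
costs at ±30%, plus the two relapse bands at ±20% relative (no published
range; a moderate default recorded in the distribution metadata).

Parameters are drawn in a fixed documented order from one seeded generator,
so a (config, n, seed) triple is bit-reproducible. The summary follows the
ratio-of-means convention: mean ICER = mean(ΔC)/mean(ΔE) over draws — with
dispersed inputs this deliberately differs from the deterministic ICER,
which is why simulated and expected-value ICERs disagree in such models.
The 95% CI is the 2.5/97.5 percentile interval of per-draw ratios among
draws with positive incremental effect (the CI construction in the source
is unstated; the quadrant tally is reported alongside so nothing is
hidden), and the CEAC at each willingness-to-pay is the fraction of draws
with positive incremental NMB — never an average of raw ratios, which is
ill-defined across quadrants.

## Numerical and testing choices

* Cent-exact arithmetic for cost line items (integer cents internally);
  model accumulators are doubles.
* Mass conservation is asserted every cycle at 1e-12 with death accumulated
  explicitly, so the check is not a tautology.
* The engine is validated against an independent individual-level
  microsimulation written separately in the test suite. Marginal occupancy
  agreement is held to a familywise max-|z| bound (marginal cells are
  serially correlated — one early fluctuation trails down a tunnel);
  one-step conditional increments, which are independent across cycles, are
  held to per-cell 3-SE agreement with the exceedance count bounded by its
  binomial null and exact Poisson bounds for sparse cells. A 40-seed
  calibration study during development confirmed the per-cell z-scores are
  unbiased with unit variance.
* Problem sizes in the shipped tests: 30,000 individuals on three
  randomised configurations plus 100,000 on the base case for the
  microsimulation cross-check; 1e-3 grid scans for the threshold searches;
  small-n PSAs for reproducibility properties. The acceptance script runs
  the full 10,000-iteration PSA. These sizes give Monte-Carlo error well
  below every tolerance used while keeping a full run in a few minutes.

## Known limitations

* The synthetic tables are anchored, not fitted; absolute long-term ICERs
  shift with the table shapes (slopes, RR floor, progression rate) even
  though orderings are stable. The generator records every shape parameter
  in `$meta` so any alternative tabulation can be dropped in as CSV.
* No smoker excess non-cancer mortality by default (a config switch on the
  mortality table would emulate it); no other smoking-related diseases, so
  QALY gains from cessation are understated and ICERs conservative.
* Relapsers never re-quit; background ("natural") quitting is assumed equal
  in both arms and is not modelled separately.
* The model is a cohort expectation; individual heterogeneity beyond the
  test-suite microsimulation (used only as an oracle) is out of scope.
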