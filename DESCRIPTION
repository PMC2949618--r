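Package: quitcea
Title: Cost-Effectiveness of Genetic-Test-Augmented Smoking Cessation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov cohort state-transition model comparing a usual
    smoking-cessation program (nicotine replacement therapy plus counselling)
    with the same program augmented by a lung-cancer susceptibility genetic
    test. Simulates a cohort of heavy smokers through five health states with
    tunnel states for time since cancer diagnosis, accumulating discounted
    costs and quality-adjusted life-years, and computes incremental
    cost-effectiveness ratios, net monetary benefit, one-way and threshold
    sensitivity analyses, break-even quit rates, scenario runs, and
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves. Includes an anchored synthetic generator for the age-indexed
    epidemiological tables (background mortality, lung-cancer incidence,
    smoker and ex-smoker relative risks, cancer survival) so the full
    pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
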