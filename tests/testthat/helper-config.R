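# Shared fixtures, built in code.

base_cfg <- function(...) ce_config(...)

# Config with every hazard switched off: nobody dies, nobody gets cancer,
# nobody relapses. Useful for closed-form reward checks.
inert_cfg <- function(horizon = 35, discount_rate = 0) {
  epi <- epi_tables()
  epi$mortality$value[] <- 0
  epi$incidence$value[] <- 0
  ce_config(
    horizon = horizon, discount_rate = discount_rate, epi = epi,
    relapse = list(years_2_6 = 0, years_7_plus = 0)
  )
}

# Constant background mortality q, no cancer, no relapse.
mortality_only_cfg <- function(q, horizon = 35, discount_rate = 0) {
  cfg <- inert_cfg(horizon = horizon, discount_rate = discount_rate)
  cfg$epi$mortality$value[] <- q
  cfg
}

# Randomised but valid configuration for property tests; rates drawn wide
# enough to exercise every transition.
random_cfg <- function() {
  epi <- epi_tables(
    mortality_anchor = runif(1, 0.002, 0.03),
    mortality_slope = runif(1, 0, 0.1),
    incidence_anchor = runif(1, 0.0005, 0.004),
    incidence_slope = runif(1, 0, 0.07),
    rr_smoker = runif(1, 3, 7),
    rr_ex_anchor = runif(1, 2, 2.9),
    rr_floor = runif(1, 1, 1.9),
    s1 = runif(1, 0.3, 0.6),
    s5 = runif(1, 0.05, 0.25)
  )
  ce_config(
    cohort_start_age = sample(35:60, 1),
    horizon = sample(10:35, 1),
    discount_rate = runif(1, 0, 0.08),
    stage_split_early = runif(1, 0.1, 0.4),
    progression_prob = runif(1, 0, 0.3),
    strategies = list(
      usc = usc_strategy(quit_rate_12m = runif(1, 0.02, 0.15)),
      gt = gt_strategy(quit_rate_12m = runif(1, 0.05, 0.3),
                       relapse_multiplier = runif(1, 0.3, 1))
    ),
    relapse = list(years_2_6 = runif(1, 0.02, 0.2),
                   years_7_plus = runif(1, 0.01, 0.08)),
    epi = epi
  )
}

# Variant of the base case where the genetic test is expensive enough that
# the GT arm is not cost-effective at the configured WTP, so threshold
# searches have a crossing inside their brackets.
dear_test_cfg <- function(test_cost = 700) {
  set_param(base_cfg(), "genetic_test_cost", test_cost)
}
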