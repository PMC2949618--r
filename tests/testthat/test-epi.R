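test_that("generated tables hit every printed anchor exactly", {
  epi <- epi_tables()
  expect_identical(epi$mortality$value[epi$mortality$age == 65], 0.00936)
  expect_identical(epi$incidence$value[epi$incidence$age == 65], 0.0018024)
  expect_identical(unname(epi$rr_current_smoker[["both"]]), 6.609)
  rr0 <- epi$rr_ex_smoker$value[epi$rr_ex_smoker$years_since_quit == 0]
  expect_true(all(rr0 == 6.609))
  anchor <- epi$rr_ex_smoker$value[epi$rr_ex_smoker$age_group == 50 &
                                     epi$rr_ex_smoker$years_since_quit == 3]
  expect_identical(anchor, 4.75)
  s_all <- epi$lc_survival[epi$lc_survival$stage == "all", ]
  expect_identical(s_all$survival[s_all$year == 1], 0.36)
  expect_identical(s_all$survival[s_all$year == 5], 0.12)
})

test_that("mortality and incidence follow the closed exponential form", {
  m <- make_mortality_table(65, 0.00936, 0.09)
  expect_equal(m$value[m$age == 85], 0.00936 * exp(0.09 * 20))
  i <- make_incidence_table(65, 0.0018024, 0.08)
  expect_equal(i$value[i$age == 55], 0.0018024 * exp(-0.8))
  # degenerate slope gives a constant table
  m0 <- make_mortality_table(65, 0.00936, 0)
  expect_true(all(m0$value == 0.00936))
  i0 <- make_incidence_table(65, 0.0018024, 0)
  expect_true(all(i0$value == 0.0018024))
  expect_error(make_mortality_table(slope = -0.1), "slope")
  expect_error(make_mortality_table(anchor_rate = 0), "anchor_rate")
})

test_that("ex-smoker RR decays monotonically from the smoker RR to the floor", {
  rr <- make_ex_smoker_rr()
  by_group <- split(rr$value, rr$age_group)
  for (v in by_group) {
    expect_true(all(diff(v) <= 0))
    expect_true(all(v >= 1.5))
    expect_true(all(v <= 6.609))
    expect_identical(v[1], 6.609)
  }
  g50 <- rr$value[rr$age_group == 50]
  expect_lt(g50[41], g50[6])      # 40 years since quit < 5 years since quit
  expect_gte(g50[41], 1.5)
  expect_error(make_ex_smoker_rr(rr_smoker = 4, anchor_value = 4.75),
               "rr_smoker >= anchor_value")
})

test_that("conditional death probabilities follow from the survival anchors", {
  curve <- lc_survival_curve(0.36, 0.12)
  pd <- survival_to_conditional_death(curve)
  expect_equal(pd$p_death[pd$year == 1], 1 - 0.36)
  # log-linear fill makes the conditional hazard constant over years 2-5
  expect_equal(pd$p_death[pd$year %in% 2:5],
               rep(1 - (0.12 / 0.36)^(1 / 4), 4))
  # degenerate: flat survival at 1 means no cancer deaths
  flat <- tibble::tibble(year = 1:5, survival = rep(1, 5))
  expect_true(all(survival_to_conditional_death(flat)$p_death == 0))
  rising <- tibble::tibble(year = 1:3, survival = c(0.5, 0.6, 0.4))
  expect_error(survival_to_conditional_death(rising), "non-increasing")
})

test_that("stage mixture reproduces the published all-stage curve exactly", {
  curve <- lc_survival_curve()
  st <- stage_survival(curve, p_early = 0.20, early_hazard_factor = 0.5)
  wide <- tidyr::pivot_wider(st, names_from = "stage", values_from = "survival")
  expect_equal(0.20 * wide$early + 0.80 * wide$advanced, wide$all)
  expect_true(all(wide$early > wide$all))      # early stage survives better
  expect_true(all(wide$advanced < wide$all))
  expect_error(stage_survival(curve, p_early = 0.9, early_hazard_factor = 0.01),
               "advanced survival")
})

test_that("generated table sets satisfy the validation invariants across settings", {
  set.seed(11)
  for (i in 1:8) {
    epi <- epi_tables(
      mortality_anchor = runif(1, 0.001, 0.05),
      mortality_slope = runif(1, 0, 0.11),
      incidence_anchor = runif(1, 0.0003, 0.01),
      incidence_slope = runif(1, 0, 0.09),
      rr_smoker = runif(1, 2.5, 9),
      rr_ex_anchor = runif(1, 1.8, 2.4),
      rr_floor = runif(1, 1, 1.7),
      s1 = runif(1, 0.25, 0.6),
      s5 = runif(1, 0.05, 0.2)
    )
    expect_silent(validate_epi(epi))
    # male risk dominates female risk
    expect_gte(epi$rr_current_smoker[["male"]], epi$rr_current_smoker[["female"]])
  }
})

test_that("epi CSV sidecars round-trip through write/read", {
  dir <- withr::local_tempdir()
  epi <- epi_tables()
  write_epi_csvs(epi, dir)
  for (f in c("mortality.csv", "incidence.csv", "rr_ex_smoker.csv",
              "lc_survival.csv")) {
    expect_true(file.exists(file.path(dir, f)))
  }
  mort <- readr::read_csv(file.path(dir, "mortality.csv"),
                          show_col_types = FALSE)
  expect_equal(mort$value, epi$mortality$value)
})
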