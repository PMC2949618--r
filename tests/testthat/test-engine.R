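test_that("death is absorbing and every transition row sums to one", {
  cfg <- base_cfg()
  dead <- build_transition_row("dead", 0, cfg)
  expect_identical(unname(dead["dead"]), 1)
  expect_identical(sum(dead), 1)
  for (arm in c("usc", "gt")) {
    for (cyc in c(0, 7, 34)) {
      for (comp in compartments()) {
        row <- build_transition_row(comp, cyc, cfg, arm)
        expect_equal(sum(row), 1, tolerance = 1e-12)
        expect_true(all(row >= 0))
      }
    }
  }
  expect_error(build_transition_row("limbo", 0, cfg), "unknown compartment")
  expect_error(build_transition_row("dead", 35, cfg), "cycle")
})

test_that("relapse and cancer-onset components match the printed rates", {
  # with mortality and incidence off, the quit->smoke entry is the relapse
  # band itself: 10% in years 2-6
  cfg <- inert_cfg()
  cfg$relapse <- list(years_2_6 = 0.10, years_7_plus = 0.04)
  row <- build_transition_row("no_lc_quit", 3, cfg)
  expect_equal(unname(row["no_lc_smoke"]), 0.10)
  row7 <- build_transition_row("no_lc_quit", 10, cfg)
  expect_equal(unname(row7["no_lc_smoke"]), 0.04)

  # cancer onset for a smoker aged 65: incidence x smoker RR, split 20/80
  cfg2 <- base_cfg()
  cfg2$epi$mortality$value[] <- 0
  cyc65 <- 65 - cfg2$cohort_start_age
  row <- build_transition_row("no_lc_smoke", cyc65, cfg2)
  onset <- unname(row["early_lc_1"] + row["adv_lc_1"])
  expect_equal(onset, 0.0018024 * 6.609)
  expect_equal(unname(row["early_lc_1"]), 0.20 * 0.0018024 * 6.609)
  expect_equal(unname(row["adv_lc_1"]), 0.80 * 0.0018024 * 6.609)
})

test_that("rewards reduce to closed forms when hazards are switched off", {
  # no deaths, no cancer, utility 1: undiscounted QALYs equal the horizon
  cfg <- inert_cfg(horizon = 35, discount_rate = 0)
  tr <- run_cohort(cfg, "usc")
  expect_equal(tr$total_qaly, 35)
  # constant mortality, no cancer, r = 0: life-years are a geometric sum
  q <- 0.05; H <- 35
  trq <- run_cohort(mortality_only_cfg(q, H), "usc")
  expect_equal(trq$total_qaly, sum((1 - q)^(0:(H - 1))), tolerance = 1e-12)
})

test_that("discounting identities hold", {
  cfg0 <- base_cfg(); cfg0$discount_rate <- 0
  tr0 <- run_cohort(cfg0, "gt")
  expect_equal(tr0$total_cost, sum(tr0$cycles$cost))
  expect_equal(tr0$total_qaly, sum(tr0$cycles$qaly))
  cfg5 <- base_cfg()
  cfg10 <- base_cfg(); cfg10$discount_rate <- 0.10
  g5 <- run_cohort(cfg5, "gt"); g10 <- run_cohort(cfg10, "gt")
  expect_lte(g10$total_cost, g5$total_cost)
  expect_lte(g10$total_qaly, g5$total_qaly)
  expect_lte(g5$total_qaly, tr0$total_qaly)
})

test_that("mass is conserved and death is monotone on randomised configurations", {
  set.seed(3)
  for (i in 1:6) {
    cfg <- random_cfg()
    for (arm in c("usc", "gt")) {
      tr <- run_cohort(cfg, arm)
      sums <- rowSums(tr$occupancy)
      expect_true(all(abs(sums - 1) < 1e-12))
      expect_true(all(tr$occupancy >= 0))
      expect_true(all(diff(tr$occupancy[, "dead"]) >= 0))
    }
  }
})

test_that("QALYs respond monotonically to quit rates and mortality", {
  cfg <- base_cfg()
  q_grid <- c(0.02, 0.06, 0.11, 0.3, 0.8)
  qalys <- vapply(q_grid, function(q) {
    run_cohort(set_param(cfg, "quit_rate_usc", q), "usc")$total_qaly
  }, numeric(1))
  expect_true(all(diff(qalys) >= 0))
  # scaling up background mortality can only lose QALYs
  hi <- cfg
  hi$epi$mortality$value <- pmin(1, hi$epi$mortality$value * 2)
  expect_lt(run_cohort(hi, "usc")$total_qaly,
            run_cohort(cfg, "usc")$total_qaly)
})

test_that("identical behavioural parameters leave only the intervention cost difference", {
  cfg <- base_cfg()
  cfg$strategies$gt$quit_rate_12m <- cfg$strategies$usc$quit_rate_12m
  res <- run_ce(cfg)
  expect_identical(res$delta_effect, 0)
  expect_equal(res$delta_cost, 355.90, tolerance = 1e-9)
  expect_identical(res$classification, "undefined")
})

test_that("cumulative relapse matches the compounding product and drops under mortality", {
  rel <- list(years_2_6 = 0.10, years_7_plus = 0.04)
  # oracle: direct product over the 35-year schedule (5 years at 10%, 29 at 4%)
  oracle <- 1 - prod(1 - c(rep(0, 1), rep(0.10, 5), rep(0.04, 29)))
  expect_equal(cumulative_relapse(rel, 35), oracle, tolerance = 1e-12)
  expect_equal(cumulative_relapse(rel, 35), 1 - 0.9^5 * 0.96^29)
  expect_identical(cumulative_relapse(list(years_2_6 = 0, years_7_plus = 0), 35), 0)
  with_mort <- cumulative_relapse(rel, 35, base_cfg())
  expect_lt(with_mort, oracle)
})

test_that("half-cycle correction is off by default and changes rewards when enabled", {
  cfg <- base_cfg()
  expect_false(cfg$half_cycle_correction)
  hc <- cfg; hc$half_cycle_correction <- TRUE
  tr <- run_cohort(cfg, "usc"); trhc <- run_cohort(hc, "usc")
  expect_false(isTRUE(all.equal(tr$total_qaly, trhc$total_qaly)))
  # occupancy itself is unaffected; only rewards move
  expect_identical(tr$occupancy, trhc$occupancy)
  # with no deaths there is nothing to correct
  expect_equal(run_cohort(inert_cfg(), "usc")$total_qaly,
               run_cohort({i <- inert_cfg(); i$half_cycle_correction <- TRUE; i},
                          "usc")$total_qaly)
})

test_that("cohort trace agrees with the individual-level microsimulation", {
  set.seed(3)
  n_ind <- 30000
  for (rep in 1:3) {
    cfg <- random_cfg()
    arm <- sample(c("usc", "gt"), 1)
    tr <- run_cohort(cfg, arm)
    occ <- microsim(cfg, arm, n_ind, seed = rep)
    chk <- microsim_check(cfg, arm, occ, tr, n_ind)
    expect_lt(chk$max_z_marginal, 4.8)
    expect_lt(chk$max_z_cond, 4.8)
    expect_lte(chk$exceed_3se, chk$exceed_3se_allowed)
    expect_true(chk$sparse_ok)
  }
})

test_that("tidy and glance expose the trace in tabular form", {
  tr <- run_cohort(base_cfg(), "gt")
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$compartment), compartments())
  expect_equal(nrow(td), (35 + 1) * 15)
  g <- glance(tr)
  expect_equal(g$total_qaly, tr$total_qaly)
  expect_s3_class(autoplot(tr), "ggplot")
})
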