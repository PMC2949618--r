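test_that("one-way sweep over the GT quit rate is strictly decreasing in ICER", {
  sweep <- one_way(base_cfg(), "quit_rate_gt", c(0.07, 0.22), steps = 6)
  expect_equal(nrow(sweep), 6)
  expect_true(all(diff(sweep$icer) < 0))
  expect_error(one_way(base_cfg(), "nonsense", c(0, 1)), "unknown parameter")
})

test_that("a zero-width range gives a constant sweep", {
  sweep <- one_way(base_cfg(), "utility_early", c(0.73, 0.73), steps = 3)
  expect_true(all(sweep$icer == sweep$icer[1]))
})

test_that("halving the genetic test cost cuts the ICER by more than 40%", {
  base <- glance(run_ce(base_cfg()))$icer
  halved <- glance(run_ce(set_param(base_cfg(), "genetic_test_cost",
                                    155.50)))$icer
  expect_lt(halved, base)
  expect_lt(halved, 0.6 * base)
})

test_that("threshold quit rate behaves in the WTP and cost limits", {
  cfg <- dear_test_cfg()
  t20 <- threshold_quit_rate(cfg, wtp = 20000)
  t_hi <- threshold_quit_rate(cfg, wtp = 5e6)
  usc_q <- cfg$strategies$usc$quit_rate_12m
  expect_gt(as.numeric(t_hi), usc_q)           # approaches USC rate from above
  expect_lt(as.numeric(t_hi), as.numeric(t20)) # decreasing in WTP
  dearer <- set_param(cfg, "genetic_test_cost", 1000)
  expect_gt(as.numeric(threshold_quit_rate(dearer)), as.numeric(t20))
  # free test with a better quit rate: dominant, no crossing in the bracket
  free <- base_cfg()
  free$strategies$gt$cost_items$unit_cost <-
    free$strategies$usc$cost_items$unit_cost[
      match(free$strategies$gt$cost_items$label,
            free$strategies$usc$cost_items$label)] |>
    (\(x) ifelse(is.na(x), 0, x))()
  tq <- threshold_quit_rate(free)
  expect_true(is.na(as.numeric(tq)))
  expect_match(attr(tq, "status"), "always cost-effective")
})

test_that("bisection thresholds agree with an exhaustive grid scan", {
  cfg <- dear_test_cfg()
  # quit-rate threshold
  tq <- as.numeric(threshold_quit_rate(cfg))
  grid <- seq(0.061, 0.5, by = 1e-3)
  f <- vapply(grid, function(q) {
    run_ce(set_param(cfg, "quit_rate_gt", q), validate = FALSE)$inmb
  }, numeric(1))
  cross <- which(diff(sign(f)) != 0)[1]
  expect_lt(abs(tq - grid[cross]), 1e-3 + 1e-9)
  # relapse-reduction threshold on the same configuration
  trr <- as.numeric(threshold_relapse_reduction(cfg))
  gridm <- seq(0, 1, by = 1e-3)
  fm <- vapply(gridm, function(m) {
    run_ce(set_param(cfg, "relapse_multiplier_gt", m), validate = FALSE)$inmb
  }, numeric(1))
  crossm <- which(diff(sign(fm)) != 0)[1]
  expect_lt(abs((1 - trr) - gridm[crossm]), 1e-3 + 1e-9)
})

test_that("break-even quit rate marks the onset of dominance", {
  cfg <- base_cfg()
  be <- as.numeric(breakeven_quit_rate(cfg))
  expect_false(is.na(be))
  # grid-scan oracle to 1e-3
  grid <- seq(0.061, 0.5, by = 1e-3)
  dc <- vapply(grid, function(q) {
    run_ce(set_param(cfg, "quit_rate_gt", q), validate = FALSE)$delta_cost
  }, numeric(1))
  cross <- which(diff(sign(dc)) != 0)[1]
  expect_lt(abs(be - grid[cross]), 1e-3 + 1e-9)
  # just above break-even the GT arm dominates
  above <- run_ce(set_param(cfg, "quit_rate_gt", be + 1e-3))
  expect_identical(above$classification, "dominant")
  below <- run_ce(set_param(cfg, "quit_rate_gt", be - 1e-3))
  expect_identical(below$classification, "tradeoff")
})

test_that("with no extra intervention cost any higher quit rate dominates", {
  cfg <- base_cfg()
  cfg$strategies$gt$cost_items <- cfg$strategies$usc$cost_items
  res <- run_ce(set_param(cfg, "quit_rate_gt", 0.07))
  expect_identical(res$classification, "dominant")
})

test_that("removing relapse lowers the break-even quit rate", {
  cfg <- base_cfg()
  be_base <- as.numeric(breakeven_quit_rate(cfg))
  cfg0 <- cfg; cfg0$relapse <- list(years_2_6 = 0, years_7_plus = 0)
  be_zero <- as.numeric(breakeven_quit_rate(cfg0))
  expect_lt(be_zero, be_base)
})

test_that("scenario orderings follow age, sex and relapse structure", {
  cfg <- base_cfg()
  base <- glance(run_ce(cfg))$icer
  age30 <- glance(scenario(cfg, start_age = 30))$icer
  age60 <- glance(scenario(cfg, start_age = 60))$icer
  expect_lt(age60, base)
  expect_lt(base, age30)
  men <- glance(scenario(cfg, sex = "male"))$icer
  women <- glance(scenario(cfg, sex = "female"))$icer
  expect_lt(men, women)
  halved <- glance(scenario(cfg, relapse_multiplier_both = 0.5))$icer
  expect_lt(halved, base)
})

test_that("a scenario with no overrides reproduces the base run bit for bit", {
  cfg <- base_cfg()
  a <- run_ce(cfg, label = "base case")
  b <- scenario(cfg)
  expect_identical(glance(a), glance(b))
  expect_identical(a$usc$occupancy, b$usc$occupancy)
})

test_that("tornado and two-way grids are well formed", {
  cfg <- base_cfg()
  ranges <- default_owsa_ranges(cfg)[1:3, ]
  tw <- tornado(cfg, ranges)
  expect_equal(nrow(tw), 3)
  expect_true(all(tw$spread >= 0))
  expect_true(all(diff(tw$spread) <= 0))
  expect_s3_class(plot_tornado(tw), "ggplot")
  grid2 <- two_way(cfg, "quit_rate_gt", c(0.08, 0.12),
                   "quit_rate_usc", c(0.04, 0.08), steps = 2)
  expect_equal(nrow(grid2), 4)
})
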