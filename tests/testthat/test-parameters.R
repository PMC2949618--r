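test_that("intervention costs reproduce the published line-item totals to the cent", {
  expect_identical(intervention_cost(usc_strategy()), 802.10)
  expect_identical(intervention_cost(gt_strategy()), 1158.00)
  empty <- strategy("none", tibble::tibble(label = character(),
                                           quantity = numeric(),
                                           unit_cost = numeric()),
                    quit_rate_12m = 0.1)
  expect_identical(intervention_cost(empty), 0)
})

test_that("intervention cost is linear in the item list", {
  set.seed(7)
  for (i in 1:10) {
    items1 <- tibble::tibble(label = letters[1:4],
                             quantity = sample(0:6, 4, replace = TRUE),
                             unit_cost = round(runif(4, 0, 400), 2))
    items2 <- tibble::tibble(label = letters[5:7],
                             quantity = sample(0:6, 3, replace = TRUE),
                             unit_cost = round(runif(3, 0, 400), 2))
    s1 <- strategy("a", items1, 0.1)
    s2 <- strategy("b", items2, 0.1)
    s12 <- strategy("ab", dplyr::bind_rows(items1, items2), 0.1)
    expect_equal(intervention_cost(s12),
                 intervention_cost(s1) + intervention_cost(s2))
  }
})

test_that("validation rejects out-of-range values and names the field", {
  expect_error(usc_strategy(quit_rate_12m = 1.3), "quit_rate_12m")
  expect_error(gt_strategy(relapse_multiplier = -0.1), "relapse_multiplier")
  expect_error(ce_config(discount_rate = 1), "discount_rate")
  expect_error(ce_config(stage_split_early = 1.7), "stage_split_early")
  cfg <- ce_config()
  cfg$utilities$early_lc <- 1.2
  expect_error(validate_config(cfg), "utilities\\$early_lc")
  cfg <- ce_config()
  cfg$cancer_costs$progressive <- -5
  expect_error(validate_config(cfg), "cancer_costs\\$progressive")
  # horizon outrunning table coverage is a coverage error, reported as such
  expect_error(ce_config(cohort_start_age = 80, horizon = 35), "coverage")
})

test_that("packaged base case loads with the published quit rates and discounts", {
  path <- system.file("extdata", "basecase.yaml", package = "quitcea")
  cfg <- load_config(path)
  expect_equal(cfg$strategies$gt$quit_rate_12m, 0.11)
  expect_equal(cfg$strategies$usc$quit_rate_12m, 0.06)
  expect_equal(cfg$discount_rate, 0.05)
  expect_equal(cfg$wtp, 20000)
  expect_equal(cfg$stage_split_early, 0.20)
})

test_that("zero discount rate is accepted and gives unit discount factors", {
  cfg <- ce_config(discount_rate = 0)
  tr <- run_cohort(cfg, "usc")
  expect_true(all(tr$cycles$discount == 1))
  expect_equal(tr$cycles$disc_cost, tr$cycles$cost)
})

test_that("config round-trips through YAML + CSV sidecars unchanged", {
  dir <- withr::local_tempdir()
  cfg <- ce_config()
  path <- write_config(cfg, dir)
  cfg2 <- load_config(path)
  expect_equal(cfg2, cfg, tolerance = 1e-12)
  # and a second write of the reloaded config is stable too
  dir2 <- withr::local_tempdir()
  cfg3 <- load_config(write_config(cfg2, dir2))
  expect_equal(cfg3, cfg2, tolerance = 1e-12)
})

test_that("missing config fields are reported by name", {
  dir <- withr::local_tempdir()
  path <- write_config(ce_config(), dir)
  doc <- yaml::read_yaml(path)
  doc$model$discount_rate <- NULL
  yaml::write_yaml(doc, path)
  expect_error(load_config(path), "discount_rate")
})

test_that("parameter registry reaches every advertised parameter", {
  cfg <- ce_config()
  for (nm in param_names()) {
    base <- get_param(cfg, nm)
    expect_true(is.numeric(base), label = nm)
    v <- if (nm %in% c("quit_rate_gt", "quit_rate_usc", "relapse_y2_6",
                       "relapse_y7plus", "stage_split_early", "utility_early",
                       "utility_advanced", "relapse_multiplier_gt",
                       "discount_rate", "progression_prob")) {
      base * 0.9
    } else {
      base * 1.1
    }
    cfg2 <- set_param(cfg, nm, v)
    expect_equal(get_param(cfg2, nm), v, label = nm)
  }
  expect_error(set_param(cfg, "no_such_parameter", 1), "unknown parameter")
})

test_that("every default PSA distribution names a real model parameter", {
  cfg <- ce_config()
  dists <- default_psa_distributions(cfg)
  expect_true(all(names(dists) %in% param_names()))
  cfg$psa <- dists
  expect_silent(validate_config(cfg))
  cfg$psa <- c(dists, list(bogus = dist_spec("fixed", 1)))
  expect_error(validate_config(cfg), "bogus")
})
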