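#' Define an intervention strategy
#'
#' A strategy bundles the one-off intervention cost line items with the
#' behavioural parameters that distinguish the two arms of the model: the
#' 12-month continuous-abstinence quit rate and a multiplier on the shared
#' annual relapse schedule.
#'
#' @param name Strategy label.
#' @param cost_items Data frame with columns `label`, `quantity`, `unit_cost`
#'   (2009 AU$). Line total is `quantity * unit_cost`.
#' @param quit_rate_12m Probability of 12-month continuous abstinence.
#' @param relapse_multiplier Non-negative factor in `[0, 1]` scaling the shared
#'   annual relapse schedule for this arm (1 = baseline schedule).
#' @return A list of class `"cea_strategy"`.
#' @export
#' @examples
#' usc <- usc_strategy()
#' intervention_cost(usc)
strategy <- function(name, cost_items, quit_rate_12m, relapse_multiplier = 1) {
  cost_items <- tibble::as_tibble(cost_items)
  out <- structure(
    list(
      name = name,
      cost_items = cost_items,
      quit_rate_12m = quit_rate_12m,
      relapse_multiplier = relapse_multiplier
    ),
    class = "cea_strategy"
  )
  validate_strategy(out)
  out
}

validate_strategy <- function(s) {
  req <- c("label", "quantity", "unit_cost")
  if (!all(req %in% names(s$cost_items))) {
    stop("cost_items must have columns label, quantity, unit_cost", call. = FALSE)
  }
  if (any(s$cost_items$quantity < 0)) {
    stop("cost_items$quantity must be >= 0 (strategy '", s$name, "')", call. = FALSE)
  }
  if (any(s$cost_items$unit_cost < 0)) {
    stop("cost_items$unit_cost must be >= 0 (strategy '", s$name, "')", call. = FALSE)
  }
  if (!is.numeric(s$quit_rate_12m) || s$quit_rate_12m < 0 || s$quit_rate_12m > 1) {
    stop("quit_rate_12m must lie in [0, 1] (strategy '", s$name, "')", call. = FALSE)
  }
  if (s$relapse_multiplier < 0 || s$relapse_multiplier > 1) {
    stop("relapse_multiplier must lie in [0, 1] (strategy '", s$name, "')", call. = FALSE)
  }
  invisible(s)
}

#' @export
print.cea_strategy <- function(x, ...) {
  cat("<cea_strategy> ", x$name, "\n", sep = "")
  cat("  quit rate (12 m): ", format(x$quit_rate_12m), "\n", sep = "")
  cat("  relapse multiplier: ", format(x$relapse_multiplier), "\n", sep = "")
  cat("  intervention cost: $", sprintf("%.2f", intervention_cost(x)), "\n", sep = "")
  invisible(x)
}

#' Total one-off intervention cost of a strategy
#'
#' Sums `quantity * unit_cost` over the cost line items, carried out in integer
#' cents so the result is exact to the cent.
#'
#' @param strategy A [strategy()] object.
#' @return Cost per person in 2009 AU$ (numeric scalar).
#' @export
intervention_cost <- function(strategy) {
  items <- strategy$cost_items
  if (nrow(items) == 0) return(0)
  cents <- round(items$unit_cost * 100)
  sum(items$quantity * cents) / 100
}

#' Usual smoking-cessation strategy (NRT + counselling)
#'
#' Cost line items: one standard GP visit, a 10-week nicotine-patch course in
#' three step-down doses, an initial plus four telephone counselling sessions,
#' and a self-help booklet. Base quit rate 6% (12-month continuous abstinence).
#'
#' @param quit_rate_12m 12-month quit rate; default 0.06.
#' @param relapse_multiplier Relapse schedule multiplier; default 1.
#' @return A `cea_strategy`.
#' @export
usc_strategy <- function(quit_rate_12m = 0.06, relapse_multiplier = 1) {
  strategy(
    name = "USC (NRT + counselling)",
    cost_items = usc_cost_items(),
    quit_rate_12m = quit_rate_12m,
    relapse_multiplier = relapse_multiplier
  )
}

usc_cost_items <- function() {
  tibble::tribble(
    ~label,                       ~quantity, ~unit_cost,
    "GP visit",                   1,         21.00,
    "Patches step 1 (21 mg)",     6,         47.95,
    "Patches step 2 (14 mg)",     2,         27.95,
    "Patches step 3 (7 mg)",      2,         27.95,
    "Telephone counselling",      5,         75.74,
    "Self-help booklet",          1,         2.90
  )
}

#' Genetic-test strategy (USC plus lung-cancer susceptibility test)
#'
#' The usual program plus two additional clinic visits, the genetic test
#' (blood sample, transfer and analysis) and a booklet explaining the results.
#' Base quit rate 11%.
#'
#' @inheritParams usc_strategy
#' @return A `cea_strategy`.
#' @export
gt_strategy <- function(quit_rate_12m = 0.11, relapse_multiplier = 1) {
  strategy(
    name = "USC + genetic test",
    cost_items = dplyr::bind_rows(
      usc_cost_items(),
      tibble::tribble(
        ~label,             ~quantity, ~unit_cost,
        "Clinic visits",    2,         21.00,
        "Genetic test",     1,         311.00,
        "Test booklet",     1,         2.90
      )
    ),
    quit_rate_12m = quit_rate_12m,
    relapse_multiplier = relapse_multiplier
  )
}

#' Annual relapse probability by years since quitting
#'
#' The shared relapse schedule is a two-band step function: no relapse in the
#' first year (the quit rate is already 12-month continuous abstinence), one
#' rate in years 2-6 and a lower rate thereafter.
#'
#' @param relapse List with elements `years_2_6` and `years_7_plus`.
#' @param years_since_quit Integer vector (>= 0).
#' @return Vector of annual relapse probabilities.
#' @export
relapse_prob <- function(relapse, years_since_quit) {
  dplyr::case_when(
    years_since_quit < 2 ~ 0,
    years_since_quit <= 6 ~ relapse$years_2_6,
    TRUE ~ relapse$years_7_plus
  )
}

default_utilities <- function() {
  list(no_lung_cancer = 1, early_lc = 0.73, advanced_lc = 0.66, dead = 0)
}

default_cancer_costs <- function() {
  list(
    early_first_year = 44274,
    advanced_first_year = 27057,
    ongoing_stable = 7115,
    progressive = 10945,
    terminal_final_year = 9961
  )
}

#' Assemble a full model configuration
#'
#' The configuration is the single object every pipeline stage consumes: the
#' cohort definition, the two strategies, the relapse schedule, utilities,
#' lung-cancer cost schedule, the age-indexed epidemiological tables and the
#' distribution assignments for probabilistic sensitivity analysis.
#'
#' Defaults encode the base case: a cohort of 50-year-old heavy smokers
#' followed for 35 annual cycles, costs and QALYs discounted at 5% a year,
#' willingness to pay $20,000 per QALY, incident cancers split 20% early /
#' 80% advanced stage.
#'
#' @param cohort_start_age Age at cycle 0 (years).
#' @param horizon Number of annual cycles.
#' @param discount_rate Annual discount rate applied to both costs and QALYs.
#' @param wtp Willingness to pay per QALY (AU$).
#' @param stage_split_early Fraction of incident lung cancers that are early
#'   stage (I/II); the remainder are advanced (III/IV).
#' @param sex One of `"both"`, `"male"`, `"female"`.
#' @param progression_prob Annual probability that an early-stage cancer in its
#'   5-year tunnel progresses to advanced stage.
#' @param half_cycle_correction Use mid-cycle occupancy for state rewards;
#'   off by default.
#' @param strategies Named list with elements `usc` and `gt` ([strategy()]).
#' @param relapse List `years_2_6`, `years_7_plus` (annual probabilities).
#' @param utilities,cancer_costs Named lists; see defaults.
#' @param epi An [epi_tables()] object; defaults to the anchored synthetic set.
#' @param psa Named list of [dist_spec()] objects; `NULL` means
#'   [default_psa_distributions()] is applied lazily by the PSA.
#' @return A list of class `"ce_config"`.
#' @export
#' @examples
#' cfg <- ce_config()
#' cfg$strategies$gt$quit_rate_12m
ce_config <- function(cohort_start_age = 50,
                      horizon = 35,
                      discount_rate = 0.05,
                      wtp = 20000,
                      stage_split_early = 0.20,
                      sex = c("both", "male", "female"),
                      progression_prob = 0.15,
                      half_cycle_correction = FALSE,
                      strategies = list(usc = usc_strategy(), gt = gt_strategy()),
                      relapse = list(years_2_6 = 0.10, years_7_plus = 0.04),
                      utilities = default_utilities(),
                      cancer_costs = default_cancer_costs(),
                      epi = epi_tables(),
                      psa = NULL) {
  sex <- match.arg(sex)
  cfg <- structure(
    list(
      cohort_start_age = cohort_start_age,
      horizon = horizon,
      discount_rate = discount_rate,
      wtp = wtp,
      stage_split_early = stage_split_early,
      sex = sex,
      progression_prob = progression_prob,
      half_cycle_correction = half_cycle_correction,
      strategies = strategies,
      relapse = relapse,
      utilities = utilities,
      cancer_costs = cancer_costs,
      epi = epi,
      psa = psa
    ),
    class = "ce_config"
  )
  validate_config(cfg)
  cfg
}

#' Validate a model configuration
#'
#' Checks every structural invariant and reports the offending parameter by
#' name. Called by [ce_config()] and [load_config()]; exported so programmatic
#' edits can be re-checked.
#'
#' @param config A `ce_config`.
#' @return The config, invisibly; errors otherwise.
#' @export
validate_config <- function(config) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("invalid config: `", field, "` ", msg, call. = FALSE)
  }
  chk(is.numeric(config$horizon) && config$horizon >= 1, "horizon", "must be >= 1")
  chk(config$discount_rate >= 0 && config$discount_rate < 1,
      "discount_rate", "must lie in [0, 1)")
  chk(config$wtp >= 0, "wtp", "must be >= 0")
  chk(config$stage_split_early >= 0 && config$stage_split_early <= 1,
      "stage_split_early", "must lie in [0, 1]")
  chk(config$progression_prob >= 0 && config$progression_prob <= 1,
      "progression_prob", "must lie in [0, 1]")
  chk(config$sex %in% c("both", "male", "female"), "sex",
      "must be one of both/male/female")
  chk(all(c("usc", "gt") %in% names(config$strategies)), "strategies",
      "must contain elements `usc` and `gt`")
  for (s in config$strategies) validate_strategy(s)
  for (band in c("years_2_6", "years_7_plus")) {
    p <- config$relapse[[band]]
    chk(is.numeric(p) && p >= 0 && p <= 1, paste0("relapse$", band),
        "must be a probability in [0, 1]")
  }
  for (u in c("no_lung_cancer", "early_lc", "advanced_lc", "dead")) {
    v <- config$utilities[[u]]
    chk(is.numeric(v) && v >= 0 && v <= 1, paste0("utilities$", u),
        "must lie in [0, 1]")
  }
  chk(config$utilities$dead == 0, "utilities$dead", "must be 0")
  for (cc in names(default_cancer_costs())) {
    v <- config$cancer_costs[[cc]]
    chk(is.numeric(v) && v >= 0, paste0("cancer_costs$", cc), "must be >= 0")
  }
  validate_epi(config$epi)
  max_age <- config$cohort_start_age + config$horizon - 1
  chk(max_age <= max(config$epi$mortality$age),
      "horizon", paste0("requires mortality table coverage to age ", max_age))
  chk(max_age <= max(config$epi$incidence$age),
      "horizon", paste0("requires incidence table coverage to age ", max_age))
  # relapse schedule is a total step function, so it covers any horizon; the
  # bands above are the whole schedule
  if (!is.null(config$psa)) {
    for (nm in names(config$psa)) {
      if (!nm %in% param_names()) {
        stop("invalid config: psa distribution `", nm,
             "` does not name a model parameter", call. = FALSE)
      }
    }
  }
  invisible(config)
}

#' @export
print.ce_config <- function(x, ...) {
  cat("<ce_config>\n")
  cat("  cohort: age ", x$cohort_start_age, ", ", x$horizon,
      " annual cycles, sex = ", x$sex, "\n", sep = "")
  cat("  discounting: ", x$discount_rate * 100, "% | WTP: $", x$wtp,
      " per QALY\n", sep = "")
  cat("  quit rates: USC ", x$strategies$usc$quit_rate_12m * 100, "%, GT ",
      x$strategies$gt$quit_rate_12m * 100, "%\n", sep = "")
  cat("  relapse: ", x$relapse$years_2_6 * 100, "% years 2-6, ",
      x$relapse$years_7_plus * 100, "% after\n", sep = "")
  invisible(x)
}

# ---- parameter registry ------------------------------------------------------
# Single place that maps sweep/PSA parameter names onto config fields, so
# one-way analyses, threshold searches and PSA all mutate the config the same
# way.

param_registry <- function() {
  list(
    quit_rate_gt = list(
      get = function(cfg) cfg$strategies$gt$quit_rate_12m,
      set = function(cfg, v) { cfg$strategies$gt$quit_rate_12m <- v; cfg }
    ),
    quit_rate_usc = list(
      get = function(cfg) cfg$strategies$usc$quit_rate_12m,
      set = function(cfg, v) { cfg$strategies$usc$quit_rate_12m <- v; cfg }
    ),
    relapse_multiplier_gt = list(
      get = function(cfg) cfg$strategies$gt$relapse_multiplier,
      set = function(cfg, v) { cfg$strategies$gt$relapse_multiplier <- v; cfg }
    ),
    relapse_y2_6 = list(
      get = function(cfg) cfg$relapse$years_2_6,
      set = function(cfg, v) { cfg$relapse$years_2_6 <- v; cfg }
    ),
    relapse_y7plus = list(
      get = function(cfg) cfg$relapse$years_7_plus,
      set = function(cfg, v) { cfg$relapse$years_7_plus <- v; cfg }
    ),
    stage_split_early = list(
      get = function(cfg) cfg$stage_split_early,
      set = function(cfg, v) { cfg$stage_split_early <- v; cfg }
    ),
    utility_early = list(
      get = function(cfg) cfg$utilities$early_lc,
      set = function(cfg, v) { cfg$utilities$early_lc <- v; cfg }
    ),
    utility_advanced = list(
      get = function(cfg) cfg$utilities$advanced_lc,
      set = function(cfg, v) { cfg$utilities$advanced_lc <- v; cfg }
    ),
    cost_early_first_year = list(
      get = function(cfg) cfg$cancer_costs$early_first_year,
      set = function(cfg, v) { cfg$cancer_costs$early_first_year <- v; cfg }
    ),
    cost_advanced_first_year = list(
      get = function(cfg) cfg$cancer_costs$advanced_first_year,
      set = function(cfg, v) { cfg$cancer_costs$advanced_first_year <- v; cfg }
    ),
    cost_ongoing_stable = list(
      get = function(cfg) cfg$cancer_costs$ongoing_stable,
      set = function(cfg, v) { cfg$cancer_costs$ongoing_stable <- v; cfg }
    ),
    cost_progressive = list(
      get = function(cfg) cfg$cancer_costs$progressive,
      set = function(cfg, v) { cfg$cancer_costs$progressive <- v; cfg }
    ),
    cost_terminal = list(
      get = function(cfg) cfg$cancer_costs$terminal_final_year,
      set = function(cfg, v) { cfg$cancer_costs$terminal_final_year <- v; cfg }
    ),
    genetic_test_cost = list(
      get = function(cfg) {
        items <- cfg$strategies$gt$cost_items
        items$unit_cost[items$label == "Genetic test"]
      },
      set = function(cfg, v) {
        items <- cfg$strategies$gt$cost_items
        items$unit_cost[items$label == "Genetic test"] <- v
        cfg$strategies$gt$cost_items <- items
        cfg
      }
    ),
    rr_current_smoker = list(
      get = function(cfg) unname(cfg$epi$rr_current_smoker["both"]),
      # rescale the excess risk of the whole RR table so ex-smoker RRs stay
      # consistent with (and below) the current-smoker RR
      set = function(cfg, v) {
        old <- unname(cfg$epi$rr_current_smoker["both"])
        f <- (v - 1) / (old - 1)
        cfg$epi$rr_current_smoker <- 1 + f * (cfg$epi$rr_current_smoker - 1)
        cfg$epi$rr_ex_smoker$value <- 1 + f * (cfg$epi$rr_ex_smoker$value - 1)
        cfg
      }
    ),
    progression_prob = list(
      get = function(cfg) cfg$progression_prob,
      set = function(cfg, v) { cfg$progression_prob <- v; cfg }
    ),
    discount_rate = list(
      get = function(cfg) cfg$discount_rate,
      set = function(cfg, v) { cfg$discount_rate <- v; cfg }
    ),
    wtp = list(
      get = function(cfg) cfg$wtp,
      set = function(cfg, v) { cfg$wtp <- v; cfg }
    )
  )
}

#' Names of the sweepable model parameters
#' @return Character vector accepted by [set_param()], [one_way()] and the PSA.
#' @export
param_names <- function() names(param_registry())

#' Get or set a model parameter by name
#'
#' @param config A `ce_config`.
#' @param name One of [param_names()].
#' @param value Replacement value.
#' @return `get_param()` the current value; `set_param()` a modified config
#'   (re-validated).
#' @export
set_param <- function(config, name, value) {
  reg <- param_registry()
  if (!name %in% names(reg)) {
    stop("unknown parameter `", name, "`; see param_names()", call. = FALSE)
  }
  cfg <- reg[[name]]$set(config, value)
  validate_config(cfg)
  cfg
}

#' @rdname set_param
#' @export
get_param <- function(config, name) {
  reg <- param_registry()
  if (!name %in% names(reg)) {
    stop("unknown parameter `", name, "`; see param_names()", call. = FALSE)
  }
  reg[[name]]$get(config)
}

# ---- file I/O ----------------------------------------------------------------

#' Read a model configuration from YAML plus sidecar CSV tables
#'
#' Scalars live in one YAML document; the age-indexed epidemiological tables
#' live in CSV files referenced by (relative) path from the YAML's `epi`
#' block. The packaged base case is
#' `system.file("extdata", "basecase.yaml", package = "quitcea")`.
#'
#' @param path Path to the YAML file.
#' @return A validated `ce_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  dir <- dirname(path)
  need <- function(block, field) {
    if (is.null(block[[field]])) {
      stop("config is missing field `", field, "`", call. = FALSE)
    }
    block[[field]]
  }
  read_items <- function(lst) {
    purrr::map_dfr(lst, ~ tibble::tibble(
      label = need(.x, "label"),
      quantity = need(.x, "quantity"),
      unit_cost = need(.x, "unit_cost")
    ))
  }
  strat <- function(block) {
    strategy(
      name = need(block, "name"),
      cost_items = read_items(need(block, "cost_items")),
      quit_rate_12m = need(block, "quit_rate_12m"),
      relapse_multiplier = block$relapse_multiplier %||% 1
    )
  }
  epi_block <- need(doc, "epi")
  rcsv <- function(f) {
    readr::read_csv(file.path(dir, need(epi_block, f)), show_col_types = FALSE,
                    progress = FALSE)
  }
  epi <- new_epi_tables(
    mortality = rcsv("mortality"),
    incidence = rcsv("incidence"),
    rr_current_smoker = unlist(need(epi_block, "rr_current_smoker")),
    rr_ex_smoker = rcsv("rr_ex_smoker"),
    lc_survival = rcsv("lc_survival"),
    meta = epi_block$meta %||% list()
  )
  model <- need(doc, "model")
  psa <- NULL
  if (!is.null(doc$psa)) {
    psa <- purrr::map(doc$psa, ~ dist_spec(
      family = need(.x, "family"),
      mean = need(.x, "mean"),
      low = .x$low %||% NA_real_,
      high = .x$high %||% NA_real_
    ))
  }
  ce_config(
    cohort_start_age = need(model, "cohort_start_age"),
    horizon = need(model, "horizon"),
    discount_rate = need(model, "discount_rate"),
    wtp = need(model, "wtp"),
    stage_split_early = need(model, "stage_split_early"),
    sex = model$sex %||% "both",
    progression_prob = model$progression_prob %||% 0.15,
    half_cycle_correction = model$half_cycle_correction %||% FALSE,
    strategies = list(
      usc = strat(need(need(doc, "strategies"), "usc")),
      gt = strat(need(need(doc, "strategies"), "gt"))
    ),
    relapse = list(
      years_2_6 = need(need(doc, "relapse"), "years_2_6"),
      years_7_plus = need(need(doc, "relapse"), "years_7_plus")
    ),
    utilities = utils::modifyList(default_utilities(),
                                  doc$utilities %||% list()),
    cancer_costs = utils::modifyList(default_cancer_costs(),
                                     doc$cancer_costs %||% list()),
    epi = epi,
    psa = psa
  )
}

#' Write a model configuration to YAML plus sidecar CSVs
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, dir))` returns a
#' configuration equal to `cfg`.
#'
#' @param config A `ce_config`.
#' @param dir Output directory (created if absent).
#' @param name Basename for the YAML file.
#' @return Path to the written YAML, invisibly.
#' @export
write_config <- function(config, dir, name = "config.yaml") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, f) {
    readr::write_csv(df, file.path(dir, f))
    f
  }
  items_list <- function(items) {
    purrr::pmap(items, function(label, quantity, unit_cost) {
      list(label = label, quantity = quantity, unit_cost = unit_cost)
    })
  }
  strat_block <- function(s) {
    list(
      name = s$name,
      quit_rate_12m = s$quit_rate_12m,
      relapse_multiplier = s$relapse_multiplier,
      cost_items = items_list(s$cost_items)
    )
  }
  doc <- list(
    model = list(
      cohort_start_age = config$cohort_start_age,
      horizon = config$horizon,
      discount_rate = config$discount_rate,
      wtp = config$wtp,
      stage_split_early = config$stage_split_early,
      sex = config$sex,
      progression_prob = config$progression_prob,
      half_cycle_correction = config$half_cycle_correction
    ),
    strategies = list(
      usc = strat_block(config$strategies$usc),
      gt = strat_block(config$strategies$gt)
    ),
    relapse = config$relapse,
    utilities = config$utilities,
    cancer_costs = config$cancer_costs,
    epi = list(
      mortality = wcsv(config$epi$mortality, "mortality.csv"),
      incidence = wcsv(config$epi$incidence, "incidence.csv"),
      rr_current_smoker = as.list(config$epi$rr_current_smoker),
      rr_ex_smoker = wcsv(config$epi$rr_ex_smoker, "rr_ex_smoker.csv"),
      lc_survival = wcsv(config$epi$lc_survival, "lc_survival.csv"),
      meta = config$epi$meta
    )
  )
  if (!is.null(config$psa)) {
    doc$psa <- purrr::map(config$psa, ~ list(
      family = .x$family, mean = .x$mean, low = .x$low, high = .x$high
    ))
  }
  path <- file.path(dir, name)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
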