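# Deterministic sensitivity analyses: one-way sweeps, tornado summaries,
# threshold and break-even searches, and named scenario runs.

#' One-way sensitivity analysis
#'
#' Re-runs the full comparison over a grid of values for one parameter, all
#' other parameters held at their configured values.
#'
#' @param config A [ce_config()].
#' @param parameter One of [param_names()].
#' @param range Length-2 numeric `c(low, high)`.
#' @param steps Number of grid points (>= 1; a zero-width range gives a
#'   constant row per point).
#' @return Tibble with one row per grid value: `parameter`, `value`,
#'   `delta_cost`, `delta_effect`, `icer`, `classification`, `inmb`.
#' @export
#' @examples
#' \donttest{
#' one_way(ce_config(), "quit_rate_gt", c(0.07, 0.22), steps = 4)
#' }
one_way <- function(config, parameter, range, steps = 5) {
  if (!parameter %in% param_names()) {
    stop("unknown parameter `", parameter, "`; see param_names()", call. = FALSE)
  }
  grid <- if (steps == 1) mean(range) else seq(range[1], range[2],
                                               length.out = steps)
  purrr::map_dfr(grid, function(v) {
    res <- run_ce(set_param(config, parameter, v), label = parameter)
    glance(res) |>
      dplyr::transmute(parameter = parameter, value = v,
                       delta_cost = .data$delta_cost,
                       delta_effect = .data$delta_effect,
                       icer = .data$icer,
                       classification = .data$classification,
                       inmb = .data$inmb)
  })
}

#' Default one-way ranges (published sensitivity ranges)
#'
#' Quit rates 7-22% (GT) and 3-12% (USC), early-stage proportion 13-23%,
#' utilities 0.69-0.83 (early) and 0.30-0.76 (advanced), all cancer costs
#' +/- 30%, and the genetic test cost halved/doubled.
#'
#' @param config A `ce_config` (supplies base cost levels).
#' @return Tibble `parameter`, `low`, `high`.
#' @export
default_owsa_ranges <- function(config) {
  cc <- config$cancer_costs
  tibble::tribble(
    ~parameter,                  ~low,                      ~high,
    "quit_rate_gt",              0.07,                      0.22,
    "quit_rate_usc",             0.03,                      0.12,
    "stage_split_early",         0.13,                      0.23,
    "utility_early",             0.69,                      0.83,
    "utility_advanced",          0.30,                      0.76,
    "cost_early_first_year",     cc$early_first_year * 0.7, cc$early_first_year * 1.3,
    "cost_advanced_first_year",  cc$advanced_first_year * 0.7, cc$advanced_first_year * 1.3,
    "cost_ongoing_stable",       cc$ongoing_stable * 0.7,   cc$ongoing_stable * 1.3,
    "cost_progressive",          cc$progressive * 0.7,      cc$progressive * 1.3,
    "cost_terminal",             cc$terminal_final_year * 0.7, cc$terminal_final_year * 1.3,
    "genetic_test_cost",         155.50,                    622.00
  )
}

#' Tornado table: ICER at each parameter's low/base/high
#'
#' @param config A `ce_config`.
#' @param ranges Tibble `parameter`, `low`, `high`; defaults to
#'   [default_owsa_ranges()].
#' @return Tibble `parameter`, `base_value`, `icer_low`, `icer_base`,
#'   `icer_high`, `spread` (absolute ICER range), sorted by spread.
#' @export
tornado <- function(config, ranges = default_owsa_ranges(config)) {
  base_icer <- glance(run_ce(config))$icer
  purrr::pmap_dfr(ranges, function(parameter, low, high) {
    g_lo <- glance(run_ce(set_param(config, parameter, low)))
    g_hi <- glance(run_ce(set_param(config, parameter, high)))
    tibble::tibble(
      parameter = parameter,
      base_value = get_param(config, parameter),
      icer_low = g_lo$icer,
      icer_base = base_icer,
      icer_high = g_hi$icer,
      spread = abs(g_hi$icer - g_lo$icer)
    )
  }) |>
    dplyr::arrange(dplyr::desc(.data$spread))
}

#' Two-way sensitivity grid
#'
#' @param config A `ce_config`.
#' @param p1,p2 Parameter names.
#' @param range1,range2 Length-2 ranges.
#' @param steps Grid points per axis.
#' @return Tibble with one row per grid cell (`value1`, `value2`, `icer`, ...).
#' @export
two_way <- function(config, p1, range1, p2, range2, steps = 5) {
  g1 <- seq(range1[1], range1[2], length.out = steps)
  g2 <- seq(range2[1], range2[2], length.out = steps)
  tidyr::expand_grid(value1 = g1, value2 = g2) |>
    purrr::pmap_dfr(function(value1, value2) {
      cfg <- set_param(set_param(config, p1, value1), p2, value2)
      glance(run_ce(cfg)) |>
        dplyr::transmute(parameter1 = p1, value1 = value1,
                         parameter2 = p2, value2 = value2,
                         delta_cost = .data$delta_cost,
                         delta_effect = .data$delta_effect,
                         icer = .data$icer,
                         classification = .data$classification)
    })
}

# Bisection on a monotone function until |f| < tol_f (or the bracket
# collapses); brackets with no sign change return NA with an explanation.
bisect <- function(f, lower, upper, tol_f = 1e-6, tol_x = 1e-10,
                   max_iter = 200) {
  fl <- f(lower); fu <- f(upper)
  if (is.na(fl) || is.na(fu) || fl * fu > 0) {
    status <- if (!is.na(fl) && !is.na(fu) && fl > 0 && fu > 0) {
      "always cost-effective in bracket"
    } else if (!is.na(fl) && !is.na(fu) && fl < 0 && fu < 0) {
      "never cost-effective in bracket"
    } else {
      "no sign change in bracket"
    }
    return(structure(NA_real_, status = status))
  }
  for (i in seq_len(max_iter)) {
    mid <- (lower + upper) / 2
    fm <- f(mid)
    if (abs(fm) < tol_f || (upper - lower) / 2 < tol_x) {
      return(structure(mid, status = "converged"))
    }
    if (fl * fm <= 0) {
      upper <- mid
    } else {
      lower <- mid; fl <- fm
    }
  }
  structure((lower + upper) / 2, status = "max iterations")
}

#' Threshold 12-month quit rate for the genetic-test arm
#'
#' Finds the GT quit rate at which the two strategies have equal net monetary
#' benefit at the given willingness to pay (incremental NMB = 0), by
#' bisection. Above this rate the genetic-test arm is cost-effective.
#'
#' @param config A `ce_config`.
#' @param wtp Willingness to pay per QALY; defaults to the configured value.
#' @param bracket Search interval for the GT quit rate.
#' @param tol_nmb Convergence tolerance on the incremental NMB (dollars).
#' @return The threshold quit rate, with attribute `status`; `NA` (with
#'   status) when the arm is never/always cost-effective in the bracket.
#' @export
threshold_quit_rate <- function(config, wtp = config$wtp,
                                bracket = c(config$strategies$usc$quit_rate_12m + 1e-6,
                                            0.5),
                                tol_nmb = 1e-6) {
  config$wtp <- wtp
  f <- function(q) {
    res <- run_ce(set_param(config, "quit_rate_gt", q))
    res$inmb
  }
  bisect(f, bracket[1], bracket[2], tol_f = tol_nmb)
}

#' Threshold relapse reduction for the genetic-test arm
#'
#' Finds the fractional reduction in the GT arm's relapse schedule (1 minus
#' the relapse multiplier) at which incremental NMB is zero at the given
#' willingness to pay, by bisection over the multiplier in `[0, 1]`. By
#' default the configured quit rates are kept, so the reduced relapse is an
#' additional benefit on top of the quit-rate difference; with
#' `equalize_quit = TRUE` the GT quit rate is first set equal to the USC
#' rate and the test's whole benefit must flow through reduced relapse. When
#' the arm is already cost-effective at the baseline schedule the search has
#' no crossing and `NA` is returned with status
#' `"always cost-effective in bracket"`.
#'
#' @inheritParams threshold_quit_rate
#' @param equalize_quit Set the GT quit rate to the USC rate before
#'   searching.
#' @return The required relapse reduction (e.g. 0.12 = relapse 12% lower than
#'   usual care), with attribute `status`.
#' @export
threshold_relapse_reduction <- function(config, wtp = config$wtp,
                                        equalize_quit = FALSE,
                                        tol_nmb = 1e-6) {
  config$wtp <- wtp
  if (equalize_quit) {
    config <- set_param(config, "quit_rate_gt",
                        config$strategies$usc$quit_rate_12m)
  }
  f <- function(m) {
    res <- run_ce(set_param(config, "relapse_multiplier_gt", m))
    res$inmb
  }
  m_star <- bisect(f, 0, 1, tol_f = tol_nmb)
  structure(1 - as.numeric(m_star), status = attr(m_star, "status"))
}

#' Break-even quit rate: when does the genetic test dominate?
#'
#' The smallest GT quit rate at which the genetic-test arm is both cheaper
#' and more effective than usual care — the point where averted lung-cancer
#' costs fully offset the additional intervention cost. Found by bisection on
#' the incremental cost (which decreases in the quit rate) over
#' `(usc quit rate, upper)`.
#'
#' @param config A `ce_config`.
#' @param upper Upper end of the search bracket.
#' @return Break-even quit rate with attribute `status`; `NA` if the arm
#'   never dominates within the bracket.
#' @export
breakeven_quit_rate <- function(config, upper = 1) {
  lower <- config$strategies$usc$quit_rate_12m + 1e-6
  f <- function(q) run_ce(set_param(config, "quit_rate_gt", q))$delta_cost
  bisect(f, lower, upper, tol_f = 1e-9, tol_x = 1e-10)
}

#' Scenario run under structural overrides
#'
#' Re-runs the full comparison with a different starting age, a single-sex
#' cohort, or a relapse multiplier applied to both arms (e.g. 0.5 for the
#' halved-relapse scenario). The horizon is kept at its configured length, so
#' an age-30 cohort is followed to 65 and an age-60 cohort to 95.
#'
#' @param config A `ce_config`.
#' @param start_age,sex Optional overrides.
#' @param relapse_multiplier_both Optional multiplier applied to both arms'
#'   relapse schedules.
#' @param label Scenario label; auto-built when `NULL`.
#' @return A `ce_result` with the label attached.
#' @export
#' @examples
#' \donttest{
#' glance(scenario(ce_config(), start_age = 60))
#' }
scenario <- function(config, start_age = NULL, sex = NULL,
                     relapse_multiplier_both = NULL, label = NULL) {
  parts <- character()
  if (!is.null(start_age)) {
    config$cohort_start_age <- start_age
    parts <- c(parts, paste0("age ", start_age))
  }
  if (!is.null(sex)) {
    config$sex <- sex
    parts <- c(parts, sex)
  }
  if (!is.null(relapse_multiplier_both)) {
    config$relapse$years_2_6 <- config$relapse$years_2_6 * relapse_multiplier_both
    config$relapse$years_7_plus <- config$relapse$years_7_plus * relapse_multiplier_both
    parts <- c(parts, paste0("relapse x ", relapse_multiplier_both))
  }
  validate_config(config)
  if (is.null(label)) {
    label <- if (length(parts)) paste(parts, collapse = ", ") else "base case"
  }
  run_ce(config, label = label)
}

#' Standard scenario battery
#'
#' Base case, cohorts starting at 30 and 60, men-only and women-only cohorts,
#' and relapse halved in both arms.
#'
#' @param config A `ce_config`.
#' @return Tibble of [glance.ce_result()] rows, one per scenario.
#' @export
run_scenarios <- function(config) {
  dplyr::bind_rows(
    glance(run_ce(config, label = "base case")),
    glance(scenario(config, start_age = 30)),
    glance(scenario(config, start_age = 60)),
    glance(scenario(config, sex = "male")),
    glance(scenario(config, sex = "female")),
    glance(scenario(config, relapse_multiplier_both = 0.5,
                    label = "relapse halved"))
  )
}

#' Tornado plot of one-way sensitivity results
#'
#' @param tornado_tbl Output of [tornado()].
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado_tbl) {
  df <- tornado_tbl |>
    dplyr::mutate(parameter = stats::reorder(.data$parameter, .data$spread))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue", alpha = 0.7) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$icer_base),
                        linetype = "dashed") +
    ggplot2::labs(x = "ICER ($ per QALY)", y = NULL,
                  title = "One-way sensitivity (low-high ICER range)") +
    ggplot2::theme_minimal()
}
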