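#' Incremental cost-effectiveness ratio with dominance classification
#'
#' Vectorised over inputs. The ratio is reported whenever the incremental
#' effect is non-zero; the classification distinguishes `dominant` (cheaper
#' and at least as effective, strictly better on one axis), `dominated`
#' (costlier and less effective), `tradeoff` (a genuine ratio), and
#' `undefined` (zero incremental effect).
#'
#' @param delta_cost Incremental cost (new minus comparator).
#' @param delta_effect Incremental effect (QALYs, quitters, ...).
#' @return Tibble with columns `delta_cost`, `delta_effect`, `icer`,
#'   `classification`.
#' @export
#' @examples
#' icer(355600, 50)   # $7,112 per additional quitter
icer <- function(delta_cost, delta_effect) {
  classification <- dplyr::case_when(
    delta_effect == 0 & delta_cost == 0 ~ "undefined",
    delta_effect == 0 ~ "undefined",
    delta_effect > 0 & delta_cost <= 0 ~ "dominant",
    delta_effect < 0 & delta_cost >= 0 ~ "dominated",
    TRUE ~ "tradeoff"
  )
  tibble::tibble(
    delta_cost = delta_cost,
    delta_effect = delta_effect,
    icer = dplyr::if_else(delta_effect != 0, delta_cost / delta_effect,
                          NA_real_),
    classification = classification
  )
}

#' Net monetary benefit
#'
#' `wtp * effect - cost`. For a strategy pair, a positive incremental NMB at
#' willingness-to-pay `wtp` is equivalent to the ICER lying below `wtp`
#' whenever the incremental effect is positive.
#'
#' @param wtp Willingness to pay per unit effect (must be `>= 0`).
#' @param cost,effect Cost and effect (vectors recycle).
#' @return Numeric NMB.
#' @export
nmb <- function(wtp, cost, effect) {
  if (any(wtp < 0)) stop("wtp must be >= 0", call. = FALSE)
  wtp * effect - cost
}

#' Short-term (12-month) comparison of the two arms
#'
#' Pure intervention-cost arithmetic at cohort scale: per-arm program cost,
#' quitters at 12 months, and the incremental cost per additional quitter.
#'
#' @param cohort Persons per arm (> 0).
#' @param usc,gt The two [strategy()] objects.
#' @return One-row tibble: `cohort_size`, `cost_usc`, `cost_gt`,
#'   `quitters_usc`, `quitters_gt`, `delta_cost`, `delta_quitters`,
#'   `cost_per_additional_quitter` (NA when the quit rates are equal).
#' @export
#' @examples
#' short_term(1000, usc_strategy(), gt_strategy())
short_term <- function(cohort, usc, gt) {
  if (cohort <= 0) stop("cohort must be > 0", call. = FALSE)
  cost_usc <- cohort * intervention_cost(usc)
  cost_gt <- cohort * intervention_cost(gt)
  quit_usc <- round(cohort * usc$quit_rate_12m)
  quit_gt <- round(cohort * gt$quit_rate_12m)
  dq <- quit_gt - quit_usc
  tibble::tibble(
    cohort_size = cohort,
    cost_usc = cost_usc,
    cost_gt = cost_gt,
    quitters_usc = quit_usc,
    quitters_gt = quit_gt,
    delta_cost = cost_gt - cost_usc,
    delta_quitters = dq,
    cost_per_additional_quitter = dplyr::if_else(dq != 0,
                                                 (cost_gt - cost_usc) / dq,
                                                 NA_real_)
  )
}

#' Run the full cost-effectiveness comparison
#'
#' Simulates both arms through the Markov cohort model and combines the
#' discounted per-person totals into the incremental result: delta cost,
#' delta QALYs, ICER (or dominance label) and incremental net monetary
#' benefit at the configured willingness to pay.
#'
#' @param config A [ce_config()].
#' @param label Optional scenario label attached to the result.
#' @param validate Passed through to [run_cohort()].
#' @return A `ce_result` with per-strategy traces and the incremental
#'   summary; see [tidy.ce_result()] and [glance.ce_result()].
#' @export
#' @examples
#' \donttest{
#' res <- run_ce(ce_config())
#' glance(res)
#' }
run_ce <- function(config, label = "base case", validate = TRUE) {
  if (validate) validate_config(config)
  tr_usc <- run_cohort(config, "usc", validate = FALSE)
  tr_gt <- run_cohort(config, "gt", validate = FALSE)
  dc <- tr_gt$total_cost - tr_usc$total_cost
  de <- tr_gt$total_qaly - tr_usc$total_qaly
  ic <- icer(dc, de)
  structure(
    list(
      label = label,
      wtp = config$wtp,
      usc = tr_usc,
      gt = tr_gt,
      delta_cost = dc,
      delta_effect = de,
      icer = ic$icer,
      classification = ic$classification,
      inmb = nmb(config$wtp, dc, de)
    ),
    class = "ce_result"
  )
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result> ", x$label, "\n", sep = "")
  cat(sprintf("  USC: $%.2f, %.4f QALYs | GT: $%.2f, %.4f QALYs\n",
              x$usc$total_cost, x$usc$total_qaly,
              x$gt$total_cost, x$gt$total_qaly))
  cat(sprintf("  delta: $%.2f, %.5f QALYs (%s)\n",
              x$delta_cost, x$delta_effect, x$classification))
  if (x$classification == "tradeoff") {
    cat(sprintf("  ICER: $%.0f per QALY\n", round(x$icer)))
  }
  cat(sprintf("  incremental NMB at WTP $%s: $%.2f\n",
              format(x$wtp, big.mark = ","), x$inmb))
  invisible(x)
}

#' Per-strategy rows of a cost-effectiveness result
#'
#' @param x A `ce_result`.
#' @param ... Unused.
#' @return Tibble with one row per strategy: discounted cost and QALYs per
#'   person.
#' @export
tidy.ce_result <- function(x, ...) {
  dplyr::bind_rows(glance(x$usc), glance(x$gt)) |>
    dplyr::mutate(label = x$label, .before = 1)
}

#' One-row incremental summary of a cost-effectiveness result
#'
#' @param x A `ce_result`.
#' @param ... Unused.
#' @return Tibble: `label`, per-arm totals, `delta_cost`, `delta_effect`,
#'   `icer`, `classification`, `inmb`, `wtp`.
#' @export
glance.ce_result <- function(x, ...) {
  tibble::tibble(
    label = x$label,
    cost_usc = x$usc$total_cost,
    cost_gt = x$gt$total_cost,
    qaly_usc = x$usc$total_qaly,
    qaly_gt = x$gt$total_qaly,
    delta_cost = x$delta_cost,
    delta_effect = x$delta_effect,
    icer = x$icer,
    classification = x$classification,
    inmb = x$inmb,
    wtp = x$wtp
  )
}

#' Export a trace or result table to CSV
#'
#' Thin wrappers writing the tidy representations; provided so pipeline runs
#' leave machine-readable artifacts.
#'
#' @param x A `cohort_trace` or `ce_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_csv <- function(x, path) {
  df <- if (inherits(x, "cohort_trace")) tidy(x) else glance(x)
  readr::write_csv(df, path)
  invisible(path)
}
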