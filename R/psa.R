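# Probabilistic sensitivity analysis.
#
# Probabilities and utilities get beta distributions, costs get gamma
# distributions (right-skewed, non-negative), both moment-matched from a
# mean and a (low, high) pair read as a central 95% interval:
# sd = (high - low) / (2 * 1.959964). Parameters are drawn in a fixed,
# documented order from a single seeded generator, so a given seed always
# reproduces the same draws.

#' Distribution assignment for one uncertain parameter
#'
#' @param family `"beta"`, `"gamma"` or `"fixed"`.
#' @param mean Central value (the deterministic base case).
#' @param low,high Endpoints of a central 95% interval (ignored for
#'   `"fixed"`).
#' @return A list of class `"dist_spec"`.
#' @export
#' @examples
#' dist_spec("beta", 0.11, 0.07, 0.22)
dist_spec <- function(family = c("beta", "gamma", "fixed"), mean,
                      low = NA_real_, high = NA_real_) {
  family <- match.arg(family)
  if (family != "fixed") {
    if (is.na(low) || is.na(high) || !(low <= mean && mean <= high)) {
      stop("need low <= mean <= high for family `", family, "`", call. = FALSE)
    }
    if (family == "beta" && (low < 0 || high > 1)) {
      stop("beta support must lie in [0, 1]", call. = FALSE)
    }
    if (family == "gamma" && low < 0) {
      stop("gamma support must be >= 0", call. = FALSE)
    }
  }
  structure(list(family = family, mean = mean, low = low, high = high),
            class = "dist_spec")
}

interval_sd <- function(low, high) (high - low) / (2 * stats::qnorm(0.975))

#' Beta shape parameters matched to a mean and 95% interval
#'
#' @param mean Mean in (0, 1).
#' @param low,high 95% interval endpoints.
#' @return Named vector `shape1`, `shape2`.
#' @export
beta_params <- function(mean, low, high) {
  v <- interval_sd(low, high)^2
  if (v >= mean * (1 - mean)) {
    stop("infeasible beta moment match: variance ", signif(v, 4),
         " >= mean*(1-mean) = ", signif(mean * (1 - mean), 4), call. = FALSE)
  }
  nu <- mean * (1 - mean) / v - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Gamma shape and rate matched to a mean and 95% interval
#'
#' @inheritParams beta_params
#' @return Named vector `shape`, `rate`.
#' @export
gamma_params <- function(mean, low, high) {
  v <- interval_sd(low, high)^2
  if (v <= 0 || mean <= 0) stop("gamma match needs mean > 0 and high > low",
                                call. = FALSE)
  c(shape = mean^2 / v, rate = mean / v)
}

draw_dist <- function(spec) {
  switch(spec$family,
    fixed = spec$mean,
    beta = {
      p <- beta_params(spec$mean, spec$low, spec$high)
      stats::rbeta(1, p[["shape1"]], p[["shape2"]])
    },
    gamma = {
      p <- gamma_params(spec$mean, spec$low, spec$high)
      stats::rgamma(1, shape = p[["shape"]], rate = p[["rate"]])
    }
  )
}

#' Default PSA distribution assignments
#'
#' Every parameter with a published one-way range, plus all lung-cancer cost
#' items: beta for the quit rates, stage split and utilities (published
#' ranges as 95% intervals), beta with a +/-20% relative interval for the
#' two relapse bands (no published range), and gamma with a +/-30% interval
#' for the five cancer costs.
#'
#' @param config A `ce_config` (supplies the central values).
#' @return Named list of [dist_spec()]s, in the fixed draw order.
#' @export
default_psa_distributions <- function(config) {
  cc <- config$cancer_costs
  rel <- config$relapse
  pm20 <- function(m) c(low = 0.8 * m, high = pmin(1, 1.2 * m))
  gamma30 <- function(m) dist_spec("gamma", m, 0.7 * m, 1.3 * m)
  r26 <- pm20(rel$years_2_6); r7 <- pm20(rel$years_7_plus)
  list(
    quit_rate_gt = dist_spec("beta", config$strategies$gt$quit_rate_12m,
                             0.07, 0.22),
    quit_rate_usc = dist_spec("beta", config$strategies$usc$quit_rate_12m,
                              0.03, 0.12),
    relapse_y2_6 = dist_spec("beta", rel$years_2_6, r26[["low"]], r26[["high"]]),
    relapse_y7plus = dist_spec("beta", rel$years_7_plus, r7[["low"]], r7[["high"]]),
    stage_split_early = dist_spec("beta", config$stage_split_early, 0.13, 0.23),
    utility_early = dist_spec("beta", config$utilities$early_lc, 0.69, 0.83),
    utility_advanced = dist_spec("beta", config$utilities$advanced_lc, 0.30, 0.76),
    cost_early_first_year = gamma30(cc$early_first_year),
    cost_advanced_first_year = gamma30(cc$advanced_first_year),
    cost_ongoing_stable = gamma30(cc$ongoing_stable),
    cost_progressive = gamma30(cc$progressive),
    cost_terminal = gamma30(cc$terminal_final_year)
  )
}

#' Draw one set of uncertain parameter values
#'
#' Draws each parameter from its assigned distribution using the current RNG
#' state, in the order the specification list is given (fixed for a given
#' distribution set, so draws are reproducible under a seed).
#'
#' @param config A `ce_config`.
#' @param distributions Named list of [dist_spec()]s; defaults to
#'   `config$psa`, falling back to [default_psa_distributions()].
#' @return Named numeric vector of drawn values.
#' @export
sample_parameters <- function(config,
                              distributions = config$psa %||%
                                default_psa_distributions(config)) {
  bad <- setdiff(names(distributions), param_names())
  if (length(bad)) {
    stop("psa distribution(s) do not name model parameters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  vapply(distributions, draw_dist, numeric(1))
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` parameter sets, re-runs both arms of the cohort model for each,
#' and summarises the paired incremental costs and effects: the mean ICER is
#' the ratio of the mean incremental cost to the mean incremental effect over
#' draws (not a mean of per-draw ratios); the 95% CI is the 2.5/97.5
#' percentile interval of per-draw ICERs among draws with positive
#' incremental effect, with the quadrant tally reported alongside; the
#' cost-effectiveness acceptability curve is the fraction of draws with
#' positive incremental net monetary benefit at each willingness-to-pay
#' value.
#'
#' @param config A `ce_config`.
#' @param n Number of iterations (>= 1).
#' @param seed Integer seed; a given (config, n, seed) triple is exactly
#'   reproducible.
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve.
#' @param distributions Named list of [dist_spec()]s; default as in
#'   [sample_parameters()].
#' @return A `psa_result`: `draws` (tibble of per-draw parameters, delta
#'   cost, delta effect), `mean_icer`, `ci95`, `ceac` tibble, `quadrants`
#'   tally, `seed`, `n`.
#' @export
#' @examples
#' \donttest{
#' p <- run_psa(ce_config(), n = 50, seed = 1)
#' glance(p)
#' }
run_psa <- function(config, n = 10000, seed = 1,
                    wtp_grid = seq(0, 100000, by = 5000),
                    distributions = config$psa %||%
                      default_psa_distributions(config)) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  validate_config(config)
  set.seed(seed)
  reg <- param_registry()
  draws <- purrr::map_dfr(seq_len(n), function(i) {
    th <- sample_parameters(config, distributions)
    cfg <- config
    for (nm in names(th)) cfg <- reg[[nm]]$set(cfg, th[[nm]])
    res <- run_ce(cfg, validate = FALSE)
    tibble::as_tibble(as.list(th)) |>
      dplyr::mutate(draw = i, delta_cost = res$delta_cost,
                    delta_effect = res$delta_effect, .before = 1)
  })

  mean_dc <- mean(draws$delta_cost)
  mean_de <- mean(draws$delta_effect)
  mean_icer <- if (mean_de != 0) mean_dc / mean_de else NA_real_

  pos <- draws$delta_effect > 0
  ratio <- draws$delta_cost[pos] / draws$delta_effect[pos]
  ci95 <- if (length(ratio) >= 2) {
    stats::quantile(ratio, c(0.025, 0.975), names = FALSE, type = 7)
  } else {
    c(NA_real_, NA_real_)
  }
  quadrants <- c(
    tradeoff_ne = sum(pos & draws$delta_cost > 0),
    dominant = sum(pos & draws$delta_cost <= 0),
    dominated = sum(!pos & draws$delta_cost >= 0 & draws$delta_effect < 0),
    tradeoff_sw = sum(draws$delta_effect < 0 & draws$delta_cost < 0),
    zero_effect = sum(draws$delta_effect == 0)
  )
  ceac <- tibble::tibble(
    wtp = wtp_grid,
    probability = vapply(wtp_grid, function(w) {
      mean(nmb(w, draws$delta_cost, draws$delta_effect) > 0)
    }, numeric(1))
  )

  structure(
    list(draws = draws, mean_icer = mean_icer,
         mean_delta_cost = mean_dc, mean_delta_effect = mean_de,
         ci95 = ci95, ceac = ceac, quadrants = quadrants,
         seed = seed, n = n, wtp = config$wtp),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result> ", x$n, " iterations (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  mean ICER (ratio of means): $%.0f per QALY\n", x$mean_icer))
  cat(sprintf("  95%% CI (percentile, positive-effect draws): $%.0f - $%.0f\n",
              x$ci95[1], x$ci95[2]))
  p20 <- x$ceac$probability[which.min(abs(x$ceac$wtp - x$wtp))]
  cat(sprintf("  P(cost-effective at WTP $%s): %.1f%%\n",
              format(x$wtp, big.mark = ","), 100 * p20))
  invisible(x)
}

#' Per-draw records of a PSA
#' @param x A `psa_result`.
#' @param ... Unused.
#' @return Tibble of draws (parameters, `delta_cost`, `delta_effect`).
#' @export
tidy.psa_result <- function(x, ...) x$draws

#' One-row summary of a PSA
#' @param x A `psa_result`.
#' @param ... Unused.
#' @return Tibble: means, mean ICER, CI bounds, CEAC at the configured WTP.
#' @export
glance.psa_result <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    seed = x$seed,
    mean_delta_cost = x$mean_delta_cost,
    mean_delta_effect = x$mean_delta_effect,
    mean_icer = x$mean_icer,
    ci_low = x$ci95[1],
    ci_high = x$ci95[2],
    prob_ce_at_wtp = x$ceac$probability[which.min(abs(x$ceac$wtp - x$wtp))],
    wtp = x$wtp
  )
}

#' Cost-effectiveness plane scatter
#'
#' One point per draw on the incremental effect / incremental cost plane,
#' with the willingness-to-pay line through the origin.
#'
#' @param object A `psa_result`.
#' @param wtp Slope of the WTP line; defaults to the configured value.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psa_result <- function(object, wtp = object$wtp, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$delta_effect, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.8, colour = "steelblue") +
    ggplot2::geom_abline(intercept = 0, slope = wtp, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (AU$)",
                  title = "Cost-effectiveness plane",
                  subtitle = sprintf("dashed line: WTP $%s per QALY",
                                     format(wtp, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve
#'
#' @param psa A `psa_result`.
#' @return A ggplot object: probability cost-effective vs willingness to pay.
#' @export
plot_ceac <- function(psa) {
  ggplot2::ggplot(psa$ceac, ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = psa$wtp, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay ($ per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}
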