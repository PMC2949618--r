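# Cohort state-transition engine.
#
# Compartments (15): the two no-cancer states, a 5-year tunnel per cancer
# stage (transition probabilities and first-year costs depend on time since
# diagnosis), a long-term "stable" survivor compartment per stage, and death.
# Years since quitting is not tunnelled: quitting happens once at cycle 0 and
# relapsers never re-quit, so years-since-quit equals the cycle index for
# every occupant of the quit state.
#
# Event ordering within a cycle is fixed and documented: background death
# first, then cancer onset (or cancer death / progression in the tunnels),
# then relapse among the remaining quitters.

TUNNEL_YEARS <- 5L

compartment_names <- function() {
  c("no_lc_quit", "no_lc_smoke",
    paste0("early_lc_", seq_len(TUNNEL_YEARS)), "early_lc_stable",
    paste0("adv_lc_", seq_len(TUNNEL_YEARS)), "adv_lc_stable",
    "dead")
}

#' Model compartments
#'
#' The five health states expand into 15 compartments: `no_lc_quit`,
#' `no_lc_smoke`, early/advanced lung-cancer tunnels (`*_1` .. `*_5`, indexed
#' by year since diagnosis), post-tunnel `*_stable` survivor compartments,
#' and absorbing `dead`.
#'
#' @return Character vector of compartment names in engine order.
#' @export
compartments <- function() compartment_names()

# Precompute every per-cycle rate the update loop needs for one arm.
engine_inputs <- function(config, arm) {
  strat <- config$strategies[[arm]]
  H <- config$horizon
  t <- seq_len(H) - 1L                      # cycle indices 0 .. H-1
  ages <- config$cohort_start_age + t
  sex <- config$sex
  epi <- config$epi

  q_bg <- epi_lookup(epi$mortality, ages, sex)
  inc <- epi_lookup(epi$incidence, ages, sex)
  rr_sm <- epi$rr_current_smoker[[sex]]
  ysq <- t + 1L                             # years since quit at cycle end
  rr_ex <- rr_ex_lookup(epi, ages, ysq, sex)
  rel <- relapse_prob(config$relapse, ysq) * strat$relapse_multiplier

  surv <- function(stage) {
    s <- epi$lc_survival[epi$lc_survival$stage == stage, ]
    survival_to_conditional_death(s)$p_death
  }

  list(
    H = H, ages = ages,
    q_bg = q_bg,
    onset_smoke = pmin(1, inc * rr_sm),
    onset_quit = pmin(1, inc * rr_ex),
    relapse = rel,
    split_early = config$stage_split_early,
    prog = config$progression_prob,
    p_death_early = surv("early"),
    p_death_adv = surv("advanced"),
    disc = (1 + config$discount_rate)^(-t),
    intervention = intervention_cost(strat)
  )
}

#' Transition probabilities out of one compartment at one cycle
#'
#' Returns the full probability row over all [compartments()] for the given
#' compartment at the end of the given cycle (0-based), under one strategy
#' arm. Rows are built from complements, so each row sums to 1 exactly; a
#' row sum outside `1 +/- 1e-9` signals a model-construction error and
#' raises, rather than being renormalised.
#'
#' @param compartment One of [compartments()].
#' @param cycle 0-based cycle index in `0 .. horizon - 1`.
#' @param config A [ce_config()].
#' @param arm `"usc"` or `"gt"`.
#' @return Named numeric vector over compartments, summing to 1.
#' @export
#' @examples
#' row <- build_transition_row("dead", 0, ce_config())
#' row["dead"]
build_transition_row <- function(compartment, cycle, config,
                                 arm = c("usc", "gt")) {
  arm <- match.arg(arm)
  comps <- compartment_names()
  if (!compartment %in% comps) {
    stop("unknown compartment `", compartment, "`", call. = FALSE)
  }
  if (cycle < 0 || cycle >= config$horizon) {
    stop("cycle must lie in 0 .. horizon - 1", call. = FALSE)
  }
  inp <- engine_inputs(config, arm)
  M <- transition_matrix(inp, cycle + 1L, config)
  row <- M[compartment, ]
  if (abs(sum(row) - 1) > 1e-9) {
    stop("transition row for `", compartment, "` sums to ", sum(row),
         "; model construction error", call. = FALSE)
  }
  row
}

# Full transition matrix at (1-based) step i. Kept as a plain function of the
# precomputed inputs so build_transition_row and the cohort loop share one
# source of truth.
transition_matrix <- function(inp, i, config) {
  comps <- compartment_names()
  n <- length(comps)
  M <- matrix(0, n, n, dimnames = list(comps, comps))
  q <- inp$q_bg[i]
  sp <- inp$split_early

  # no-cancer states: death, then onset (stage split), then relapse
  for (st in c("no_lc_quit", "no_lc_smoke")) {
    onset <- if (st == "no_lc_quit") inp$onset_quit[i] else inp$onset_smoke[i]
    rel <- if (st == "no_lc_quit") inp$relapse[i] else 0
    alive <- 1 - q
    M[st, "dead"] <- q
    M[st, "early_lc_1"] <- alive * onset * sp
    M[st, "adv_lc_1"] <- alive * onset * (1 - sp)
    stay <- alive * (1 - onset)
    M[st, "no_lc_smoke"] <- M[st, "no_lc_smoke"] + stay * rel
    M[st, st] <- M[st, st] + stay * (1 - rel)
  }

  # cancer tunnels: background death, cancer death, then progression (early)
  for (k in seq_len(TUNNEL_YEARS)) {
    nxt_e <- if (k < TUNNEL_YEARS) paste0("early_lc_", k + 1) else "early_lc_stable"
    nxt_a <- if (k < TUNNEL_YEARS) paste0("adv_lc_", k + 1) else "adv_lc_stable"
    e <- paste0("early_lc_", k)
    pd <- inp$p_death_early[k]
    s <- (1 - q) * (1 - pd)
    M[e, "dead"] <- q + (1 - q) * pd
    M[e, nxt_a] <- s * inp$prog
    M[e, nxt_e] <- s * (1 - inp$prog)
    a <- paste0("adv_lc_", k)
    pd <- inp$p_death_adv[k]
    M[a, "dead"] <- q + (1 - q) * pd
    M[a, nxt_a] <- M[a, nxt_a] + (1 - q) * (1 - pd)
  }

  # stable survivors: background mortality only
  for (st in c("early_lc_stable", "adv_lc_stable")) {
    M[st, "dead"] <- q
    M[st, st] <- 1 - q
  }

  M["dead", "dead"] <- 1
  M
}

#' Run the cohort through the model under one strategy arm
#'
#' Cycle 0 allocates `quit_rate_12m` of the cohort to `no_lc_quit` and the
#' rest to `no_lc_smoke` (everyone cancer-free in the first annual cycle).
#' State rewards (utilities and cancer care costs) accrue on the occupancy at
#' the start of each cycle and are discounted by `1 / (1 + r)^t`; transition-
#' linked costs (progressive disease on early-to-advanced moves, terminal
#' care on cancer deaths) accrue in the cycle of the transition. The one-off
#' intervention cost is charged at cycle 0, undiscounted.
#'
#' @param config A [ce_config()].
#' @param arm `"usc"` or `"gt"`.
#' @param validate Re-validate the config before running (default); inner
#'   loops that mutate parameters through the checked setters can skip it.
#' @return A `cohort_trace`: occupancy matrix (`horizon + 1` cycles by 15
#'   compartments), a per-cycle tibble of rewards and flows, and discounted
#'   totals per person. Access tidily via [tidy.cohort_trace()] /
#'   [glance.cohort_trace()].
#' @export
#' @examples
#' tr <- run_cohort(ce_config(), "usc")
#' glance(tr)
run_cohort <- function(config, arm = c("usc", "gt"), validate = TRUE) {
  arm <- match.arg(arm)
  if (validate) validate_config(config)
  inp <- engine_inputs(config, arm)
  H <- inp$H
  comps <- compartment_names()
  n <- length(comps)
  ix <- stats::setNames(seq_len(n), comps)

  occ <- matrix(0, H + 1, n, dimnames = list(0:H, comps))
  strat <- config$strategies[[arm]]
  occ[1, ix["no_lc_quit"]] <- strat$quit_rate_12m
  occ[1, ix["no_lc_smoke"]] <- 1 - strat$quit_rate_12m

  relapse_flow <- numeric(H)
  cancer_deaths <- numeric(H)
  progressions <- numeric(H)

  e1 <- ix[paste0("early_lc_", seq_len(TUNNEL_YEARS))]
  a1 <- ix[paste0("adv_lc_", seq_len(TUNNEL_YEARS))]

  for (i in seq_len(H)) {
    cur <- occ[i, ]
    nxt <- numeric(n)
    q <- inp$q_bg[i]

    # quitters
    alive <- cur[ix["no_lc_quit"]] * (1 - q)
    onset <- alive * inp$onset_quit[i]
    rem <- alive - onset
    rel <- rem * inp$relapse[i]
    relapse_flow[i] <- rel
    nxt[ix["early_lc_1"]] <- nxt[ix["early_lc_1"]] + onset * inp$split_early
    nxt[ix["adv_lc_1"]] <- nxt[ix["adv_lc_1"]] + onset * (1 - inp$split_early)
    nxt[ix["no_lc_smoke"]] <- nxt[ix["no_lc_smoke"]] + rel
    nxt[ix["no_lc_quit"]] <- rem - rel

    # smokers
    alive <- cur[ix["no_lc_smoke"]] * (1 - q)
    onset <- alive * inp$onset_smoke[i]
    nxt[ix["early_lc_1"]] <- nxt[ix["early_lc_1"]] + onset * inp$split_early
    nxt[ix["adv_lc_1"]] <- nxt[ix["adv_lc_1"]] + onset * (1 - inp$split_early)
    nxt[ix["no_lc_smoke"]] <- nxt[ix["no_lc_smoke"]] + alive - onset

    # cancer tunnels
    for (k in seq_len(TUNNEL_YEARS)) {
      last <- k == TUNNEL_YEARS
      # early stage
      s1 <- cur[e1[k]] * (1 - q)
      dcan <- s1 * inp$p_death_early[k]
      s2 <- s1 - dcan
      pr <- s2 * inp$prog
      cancer_deaths[i] <- cancer_deaths[i] + dcan
      progressions[i] <- progressions[i] + pr
      dst_a <- if (last) ix["adv_lc_stable"] else a1[k + 1]
      dst_e <- if (last) ix["early_lc_stable"] else e1[k + 1]
      nxt[dst_a] <- nxt[dst_a] + pr
      nxt[dst_e] <- nxt[dst_e] + s2 - pr
      # advanced stage
      s1 <- cur[a1[k]] * (1 - q)
      dcan <- s1 * inp$p_death_adv[k]
      cancer_deaths[i] <- cancer_deaths[i] + dcan
      dst_a <- if (last) ix["adv_lc_stable"] else a1[k + 1]
      nxt[dst_a] <- nxt[dst_a] + s1 - dcan
    }

    # stable survivors
    nxt[ix["early_lc_stable"]] <- nxt[ix["early_lc_stable"]] +
      cur[ix["early_lc_stable"]] * (1 - q)
    nxt[ix["adv_lc_stable"]] <- nxt[ix["adv_lc_stable"]] +
      cur[ix["adv_lc_stable"]] * (1 - q)

    # death accumulated explicitly (background deaths + cancer deaths), so the
    # mass-conservation check below is a real check, not a tautology
    nxt[ix["dead"]] <- cur[ix["dead"]] + q * (1 - cur[ix["dead"]]) +
      cancer_deaths[i]
    occ[i + 1, ] <- nxt
    if (abs(sum(nxt) - 1) > 1e-12) {
      stop("cohort mass not conserved at cycle ", i, call. = FALSE)
    }
  }

  u <- config$utilities
  cc <- config$cancer_costs
  u_vec <- c(u$no_lung_cancer, u$no_lung_cancer,
             rep(u$early_lc, TUNNEL_YEARS + 1),
             rep(u$advanced_lc, TUNNEL_YEARS + 1), u$dead)
  # order follows compartments(): first tunnel year carries the first-year
  # treatment cost, later tunnel years and stable survivors the ongoing cost
  cost_vec <- c(0, 0,
                cc$early_first_year, rep(cc$ongoing_stable, TUNNEL_YEARS - 1),
                cc$ongoing_stable,
                cc$advanced_first_year, rep(cc$ongoing_stable, TUNNEL_YEARS - 1),
                cc$ongoing_stable,
                0)

  reward_occ <- occ[seq_len(H), , drop = FALSE]
  if (config$half_cycle_correction) {
    reward_occ <- 0.5 * (occ[seq_len(H), , drop = FALSE] +
                           occ[seq_len(H) + 1, , drop = FALSE])
  }
  qaly <- as.numeric(reward_occ %*% u_vec)
  cost <- as.numeric(reward_occ %*% cost_vec) +
    progressions * cc$progressive +
    cancer_deaths * cc$terminal_final_year
  cost[1] <- cost[1] + inp$intervention

  cycles <- tibble::tibble(
    cycle = seq_len(H) - 1L,
    age = inp$ages,
    cost = cost,
    qaly = qaly,
    discount = inp$disc,
    disc_cost = cost * inp$disc,
    disc_qaly = qaly * inp$disc,
    relapse_flow = relapse_flow,
    cancer_deaths = cancer_deaths,
    progressions = progressions
  )

  structure(
    list(
      arm = arm,
      strategy = strat$name,
      occupancy = occ,
      cycles = cycles,
      total_cost = sum(cycles$disc_cost),
      total_qaly = sum(cycles$disc_qaly),
      start_age = config$cohort_start_age,
      horizon = H
    ),
    class = "cohort_trace"
  )
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace> ", x$strategy, "\n", sep = "")
  cat("  ", x$horizon, " cycles from age ", x$start_age, "\n", sep = "")
  cat("  discounted totals per person: $", sprintf("%.2f", x$total_cost),
      ", ", sprintf("%.4f", x$total_qaly), " QALYs\n", sep = "")
  invisible(x)
}

#' Tidy a cohort trace into long occupancy records
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return Tibble with columns `cycle`, `age`, `compartment`, `occupancy`.
#' @export
tidy.cohort_trace <- function(x, ...) {
  occ <- tibble::as_tibble(x$occupancy)
  occ$cycle <- 0:x$horizon
  occ$age <- x$start_age + occ$cycle
  tidyr::pivot_longer(occ, cols = -c("cycle", "age"),
                      names_to = "compartment", values_to = "occupancy")
}

#' One-row summary of a cohort trace
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return Tibble with the arm, discounted totals and final survival.
#' @export
glance.cohort_trace <- function(x, ...) {
  tibble::tibble(
    arm = x$arm,
    strategy = x$strategy,
    total_cost = x$total_cost,
    total_qaly = x$total_qaly,
    alive_at_end = 1 - x$occupancy[x$horizon + 1, "dead"]
  )
}

#' Plot compartment occupancy over age
#'
#' Grouped view of the cohort trace: quitters/relapsed smokers and the
#' aggregated early/advanced cancer and dead fractions by age.
#'
#' @param object A `cohort_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_trace <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(group = dplyr::case_when(
      .data$compartment == "no_lc_quit" ~ "Quit, no lung cancer",
      .data$compartment == "no_lc_smoke" ~ "Smoking, no lung cancer",
      grepl("^early", .data$compartment) ~ "Early lung cancer",
      grepl("^adv", .data$compartment) ~ "Advanced lung cancer",
      TRUE ~ "Dead"
    )) |>
    dplyr::group_by(.data$age, .data$group) |>
    dplyr::summarise(occupancy = sum(.data$occupancy), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$occupancy,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Age (years)", y = "Cohort fraction", colour = NULL,
                  title = object$strategy) +
    ggplot2::theme_minimal()
}

#' Cumulative relapse among initial quitters
#'
#' Without mortality this is the closed form `1 - prod(1 - p_t)` over the
#' years since quitting covered by the horizon. With `config` supplied, the
#' relapse transitions are summed from a full cohort run, so quitters who die
#' (or develop cancer) before relapsing are no longer at risk and the
#' cumulative relapse is strictly lower.
#'
#' @param relapse Relapse schedule (list `years_2_6`, `years_7_plus`).
#' @param horizon Years of follow-up.
#' @param config Optional `ce_config`; when supplied, compute from the cohort
#'   trace of the given arm (with its mortality and cancer risks) instead of
#'   the closed form.
#' @param arm Arm used for the trace-based computation.
#' @return Fraction of the initial quitters who ever relapse.
#' @export
#' @examples
#' cumulative_relapse(list(years_2_6 = 0.10, years_7_plus = 0.04), 35)
cumulative_relapse <- function(relapse, horizon, config = NULL,
                               arm = c("usc", "gt")) {
  arm <- match.arg(arm)
  if (is.null(config)) {
    p <- relapse_prob(relapse, seq_len(horizon))
    return(1 - prod(1 - p))
  }
  config$relapse <- relapse
  config$horizon <- horizon
  tr <- run_cohort(config, arm)
  q0 <- config$strategies[[arm]]$quit_rate_12m
  if (q0 == 0) return(0)
  sum(tr$cycles$relapse_flow) / q0
}
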