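# Independent individual-level simulator used as an oracle for the cohort
# engine. It derives every per-cycle rate directly from the config and epi
# tibbles (its own lookups, not the engine's), applies the same documented
# event ordering (background death, then cancer events, then relapse) to
# each simulated individual, and reports compartment occupancy fractions per
# cycle. Agreement between its Monte-Carlo occupancy and the engine's
# deterministic trace checks the cohort algebra end to end.

microsim_states <- function() {
  c("no_lc_quit", "no_lc_smoke",
    paste0("early_lc_", 1:5), "early_lc_stable",
    paste0("adv_lc_", 1:5), "adv_lc_stable", "dead")
}

microsim <- function(config, arm, n_ind, seed) {
  set.seed(seed)
  H <- config$horizon
  ages <- config$cohort_start_age + 0:(H - 1)
  sex <- config$sex
  epi <- config$epi

  lookup <- function(tbl, ages) {
    keep <- tbl$sex == sex
    if (!any(keep)) keep <- tbl$sex == "both"
    tbl$value[keep][match(ages, tbl$age[keep])]
  }
  q_bg <- lookup(epi$mortality, ages)
  inc <- lookup(epi$incidence, ages)
  rr_sm <- epi$rr_current_smoker[[sex]]

  rr_ex_at <- function(age, ysq) {
    grp <- min(max(30, 5 * floor(age / 5)), max(epi$rr_ex_smoker$age_group))
    ysq <- min(ysq, max(epi$rr_ex_smoker$years_since_quit))
    v <- epi$rr_ex_smoker$value[epi$rr_ex_smoker$age_group == grp &
                                  epi$rr_ex_smoker$years_since_quit == ysq]
    if (sex != "both") {
      f <- (epi$rr_current_smoker[[sex]] - 1) /
        (epi$rr_current_smoker[["both"]] - 1)
      v <- 1 + f * (v - 1)
    }
    v
  }

  relapse_at <- function(ysq) {
    p <- if (ysq < 2) 0 else if (ysq <= 6) config$relapse$years_2_6 else
      config$relapse$years_7_plus
    p * config$strategies[[arm]]$relapse_multiplier
  }

  cond_death <- function(stage) {
    s <- epi$lc_survival[epi$lc_survival$stage == stage, ]
    s <- s[order(s$year), ]
    1 - s$survival / c(1, s$survival[-nrow(s)])
  }
  pde <- cond_death("early")
  pda <- cond_death("advanced")

  st <- microsim_states()
  S <- stats::setNames(seq_along(st), st)
  quit0 <- stats::runif(n_ind) < config$strategies[[arm]]$quit_rate_12m
  state <- ifelse(quit0, S["no_lc_quit"], S["no_lc_smoke"])

  occ <- matrix(0, H + 1, length(st), dimnames = list(0:H, st))
  occ[1, ] <- tabulate(state, nbins = length(st)) / n_ind

  for (t in seq_len(H)) {
    new <- state
    alive <- state != S["dead"]
    # background death first, in every alive compartment
    dies <- alive & stats::runif(n_ind) < q_bg[t]
    new[dies] <- S["dead"]
    live <- alive & !dies

    ysq <- t  # years since quit at the end of cycle t-1 .. t is t
    for (nm in c("no_lc_quit", "no_lc_smoke")) {
      in_st <- live & state == S[nm]
      if (!any(in_st)) next
      onset_p <- if (nm == "no_lc_quit") {
        inc[t] * rr_ex_at(ages[t], ysq)
      } else {
        inc[t] * rr_sm
      }
      onset <- in_st & stats::runif(n_ind) < min(1, onset_p)
      early <- onset & stats::runif(n_ind) < config$stage_split_early
      new[early] <- S["early_lc_1"]
      new[onset & !early] <- S["adv_lc_1"]
      if (nm == "no_lc_quit") {
        stayed <- in_st & !onset
        rel <- stayed & stats::runif(n_ind) < relapse_at(ysq)
        new[rel] <- S["no_lc_smoke"]
      }
    }

    for (k in 1:5) {
      nxt_e <- if (k < 5) S[paste0("early_lc_", k + 1)] else S["early_lc_stable"]
      nxt_a <- if (k < 5) S[paste0("adv_lc_", k + 1)] else S["adv_lc_stable"]
      in_e <- live & state == S[paste0("early_lc_", k)]
      if (any(in_e)) {
        dc <- in_e & stats::runif(n_ind) < pde[k]
        new[dc] <- S["dead"]
        surv <- in_e & !dc
        pr <- surv & stats::runif(n_ind) < config$progression_prob
        new[pr] <- nxt_a
        new[surv & !pr] <- nxt_e
      }
      in_a <- live & state == S[paste0("adv_lc_", k)]
      if (any(in_a)) {
        dc <- in_a & stats::runif(n_ind) < pda[k]
        new[dc] <- S["dead"]
        new[in_a & !dc] <- nxt_a
      }
    }
    # stable compartments only face background death, already applied

    state <- new
    occ[t + 1, ] <- tabulate(state, nbins = length(st)) / n_ind
  }
  occ
}

# Compare a microsim run against the engine, two ways.
#
# Marginal: microsim occupancy vs the engine's deterministic occupancy; the
# count in each (cycle, compartment) cell is Binomial(n_ind, p_engine), so
# dense cells get normal z-scores. Cells are strongly correlated across
# cycles (one early fluctuation trails down a tunnel), so only a familywise
# max-|z| bound is meaningful here.
#
# Conditional: each cycle's microsim counts vs its OWN previous counts
# pushed through the engine's transition rows. Given the previous state the
# destination counts are sums of independent Bernoullis, with
# mu_j = sum_i c_i P_ij and var_j = sum_i c_i P_ij (1 - P_ij), and the
# increments are independent across cycles — so per-cell criteria are
# correctly calibrated. Dense cells (mu >= 5) use z-scores; sparse cells are
# held to Poisson 1e-5 tail bounds.
microsim_check <- function(config, arm, occ_ms, trace, n_ind) {
  comps <- microsim_states()
  H <- config$horizon
  counts <- round(occ_ms * n_ind)

  p <- trace$occupancy[, comps]
  se <- sqrt(p * (1 - p) / n_ind)
  zmarg <- (occ_ms - p) / se
  zmarg[se == 0] <- ifelse(abs(occ_ms - p)[se == 0] < 1e-12, 0, Inf)
  dense_m <- n_ind * p >= 5 & n_ind * (1 - p) >= 5

  zcond <- c()
  sparse_ok <- TRUE
  for (t in seq_len(H)) {
    M <- t(vapply(comps, function(cp) {
      build_transition_row(cp, t - 1, config, arm)[comps]
    }, numeric(length(comps))))
    c_prev <- counts[t, ]
    mu <- as.numeric(c_prev %*% M)
    v <- as.numeric(c_prev %*% (M * (1 - M)))
    obs <- counts[t + 1, ]
    dense <- mu >= 20 & v > 0
    zcond <- c(zcond, (obs[dense] - mu[dense]) / sqrt(v[dense]))
    sp <- !dense
    if (any(sp)) {
      lo <- stats::qpois(1e-5, mu[sp])
      hi <- stats::qpois(1 - 1e-5, mu[sp])
      sparse_ok <- sparse_ok && all(obs[sp] >= lo & obs[sp] <= hi)
    }
  }
  # the number of cells beyond 3 SE has a known binomial null; "agreement on
  # the 3-SE scale" means that count is no larger than its 99.9% quantile
  n_cells <- length(zcond)
  exceed <- sum(abs(zcond) > 3)
  list(
    max_z_marginal = if (any(dense_m)) max(abs(zmarg[dense_m])) else 0,
    max_z_cond = max(abs(zcond)),
    exceed_3se = exceed,
    exceed_3se_allowed = stats::qbinom(0.999, n_cells, 0.004),
    sparse_ok = sparse_ok
  )
}
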