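# Anchored synthetic epidemiological tables.
#
# The model consumes four age/time-indexed tables that national statistics
# normally supply: background all-cause mortality, lung-cancer incidence in
# the general population, relative risks for current and ex-smokers, and
# lung-cancer survival by year since diagnosis. The generators below produce
# smooth parametric tables pinned exactly to published single-age anchor
# values, so the whole pipeline runs self-contained and deterministically
# (no seed, no download).

#' Background all-cause mortality table
#'
#' Gompertz-type hazard: `q(age) = min(1, anchor_rate * exp(slope * (age -
#' anchor_age)))`, anchored so `q(anchor_age)` equals the anchor exactly.
#' Default anchor: annual death probability 0.00936 at age 65.
#'
#' @param anchor_age Age at which the anchor rate applies.
#' @param anchor_rate Annual death probability at `anchor_age`, in (0, 1).
#' @param slope Exponential slope per year of age; `>= 0` (0 gives a constant
#'   table).
#' @param ages Integer ages covered.
#' @return Tibble with columns `age`, `sex` (`"both"`), `value`.
#' @export
#' @examples
#' tab <- make_mortality_table()
#' tab$value[tab$age == 65]
make_mortality_table <- function(anchor_age = 65, anchor_rate = 0.00936,
                                 slope = 0.09, ages = 30:100) {
  if (!(anchor_rate > 0 && anchor_rate < 1)) {
    stop("anchor_rate must lie in (0, 1)", call. = FALSE)
  }
  if (slope < 0) stop("slope must be >= 0", call. = FALSE)
  tibble::tibble(
    age = ages,
    sex = "both",
    value = pmin(1, anchor_rate * exp(slope * (ages - anchor_age)))
  )
}

#' Lung-cancer incidence table (general population)
#'
#' Exponential-in-age incidence anchored at a printed single-age value
#' (default: annual probability 0.0018024 at age 65).
#'
#' @inheritParams make_mortality_table
#' @return Tibble with columns `age`, `sex`, `value`.
#' @export
make_incidence_table <- function(anchor_age = 65, anchor_rate = 0.0018024,
                                 slope = 0.08, ages = 30:100) {
  if (!(anchor_rate > 0 && anchor_rate < 1)) {
    stop("anchor_rate must lie in (0, 1)", call. = FALSE)
  }
  if (slope < 0) stop("slope must be >= 0", call. = FALSE)
  tibble::tibble(
    age = ages,
    sex = "both",
    value = pmin(1, anchor_rate * exp(slope * (ages - anchor_age)))
  )
}

#' Ex-smoker relative risk by age group and years since quitting
#'
#' Exponential decay from the current-smoker relative risk toward a floor
#' above 1 (ex-smoker risk stays elevated indefinitely):
#' `rr(t) = floor + (rr_smoker - floor) * exp(-k * t)`, with the decay rate
#' `k` solved so the curve passes exactly through the anchor value at the
#' anchor years-since-quit (default: RR 4.75 for the 50-55 age group at 3
#' years since quitting, the midpoint of that group's first 5 quit years for
#' a cohort quitting at 50). The same decay is applied in every 5-year age
#' group; the age-group index is kept so calibrated group-specific tables can
#' be dropped in.
#'
#' @param rr_smoker Current-smoker relative risk (value at 0 years since quit).
#' @param anchor_value RR the curve must pass through.
#' @param anchor_ysq Years since quitting at which `anchor_value` applies.
#' @param floor Asymptotic RR, `>= 1`.
#' @param age_groups Starting ages of the 5-year groups.
#' @param max_ysq Largest years-since-quit tabulated.
#' @return Tibble with columns `age_group`, `years_since_quit`, `value`.
#' @export
make_ex_smoker_rr <- function(rr_smoker = 6.609, anchor_value = 4.75,
                              anchor_ysq = 3, floor = 1.5,
                              age_groups = seq(30, 95, by = 5),
                              max_ysq = 60) {
  if (!(rr_smoker >= anchor_value && anchor_value >= floor && floor >= 1)) {
    stop("need rr_smoker >= anchor_value >= floor >= 1", call. = FALSE)
  }
  k <- -log((anchor_value - floor) / (rr_smoker - floor)) / anchor_ysq
  ysq <- 0:max_ysq
  decay <- floor + (rr_smoker - floor) * exp(-k * ysq)
  # pin the anchor exactly (exp/log round-trip is within 1 ulp; force it)
  decay[ysq == anchor_ysq] <- anchor_value
  tidyr::expand_grid(age_group = age_groups, years_since_quit = ysq) |>
    dplyr::mutate(value = rep(decay, times = length(age_groups)))
}

#' Convert cumulative lung-cancer survival to per-cycle death probabilities
#'
#' Given cumulative survival anchors S(1) and S(5) (years since diagnosis),
#' fills years 2-4 by log-linear interpolation and returns the conditional
#' annual death probability `p(k) = 1 - S(k)/S(k-1)` with `S(0) = 1`. Beyond
#' year 5 the excess cancer hazard is taken to be zero (stable-disease
#' survivorship: background mortality only), which is the engine's tail rule.
#'
#' @param survival Tibble/data frame with columns `year` (1..5) and
#'   `survival` (cumulative, decreasing, in (0, 1]).
#' @return Tibble with columns `year`, `p_death`.
#' @export
#' @examples
#' survival_to_conditional_death(lc_survival_curve(0.36, 0.12))
survival_to_conditional_death <- function(survival) {
  o <- order(survival$year)
  yr <- survival$year[o]
  sv <- survival$survival[o]
  if (any(diff(sv) > 0)) {
    stop("cumulative survival must be non-increasing in year", call. = FALSE)
  }
  if (any(sv <= 0 | sv > 1)) {
    stop("cumulative survival must lie in (0, 1]", call. = FALSE)
  }
  prev <- c(1, sv[-length(sv)])
  tibble::tibble(year = yr, p_death = 1 - sv / prev)
}

#' Cumulative survival curve through printed anchors
#'
#' Log-linear interpolation between S(1) and S(5); both anchors reproduced
#' exactly.
#'
#' @param s1,s5 Cumulative survival at 1 and 5 years since diagnosis.
#' @return Tibble `year` (1..5), `survival`.
#' @export
lc_survival_curve <- function(s1 = 0.36, s5 = 0.12) {
  year <- 1:5
  tibble::tibble(year = year, survival = s1 * (s5 / s1)^((year - 1) / 4))
}

#' Stage-specific survival from the all-stage curve
#'
#' The published curve is all-stage. Early-stage survival is defined by a
#' proportional-hazards factor `early_hazard_factor < 1` applied to the
#' all-stage curve (`S_early = S^h`); advanced-stage survival is the residual
#' that makes the stage mixture reproduce the published curve exactly at
#' every year: `p * S_early + (1 - p) * S_adv = S`.
#'
#' @param survival All-stage curve ([lc_survival_curve()]).
#' @param p_early Early-stage fraction of incident cancers.
#' @param early_hazard_factor Hazard multiplier for early stage, in (0, 1].
#' @return Tibble `year`, `stage` (all/early/advanced), `survival`.
#' @export
stage_survival <- function(survival, p_early = 0.20, early_hazard_factor = 0.5) {
  s <- survival$survival
  se <- s^early_hazard_factor
  sa <- (s - p_early * se) / (1 - p_early)
  if (any(sa <= 0)) {
    stop("early_hazard_factor too small: implied advanced survival <= 0",
         call. = FALSE)
  }
  dplyr::bind_rows(
    tibble::tibble(year = survival$year, stage = "all", survival = s),
    tibble::tibble(year = survival$year, stage = "early", survival = se),
    tibble::tibble(year = survival$year, stage = "advanced", survival = sa)
  )
}

new_epi_tables <- function(mortality, incidence, rr_current_smoker,
                           rr_ex_smoker, lc_survival, meta = list()) {
  structure(
    list(
      mortality = tibble::as_tibble(mortality),
      incidence = tibble::as_tibble(incidence),
      rr_current_smoker = rr_current_smoker,
      rr_ex_smoker = tibble::as_tibble(rr_ex_smoker),
      lc_survival = tibble::as_tibble(lc_survival),
      meta = meta
    ),
    class = "epi_tables"
  )
}

#' Assemble the full anchored synthetic epidemiological table set
#'
#' Bundles [make_mortality_table()], [make_incidence_table()],
#' [make_ex_smoker_rr()] and [stage_survival()] into the object the engine
#' consumes, together with per-sex current-smoker relative risks. Sex
#' differences enter through the relative-risk excess: the male (female)
#' current-smoker RR is `1 + m * (rr_smoker - 1)` with multiplier `m` above
#' (below) 1, reflecting heavier smoking histories in men; ex-smoker RRs are
#' scaled by the same factor at lookup time. All generator settings are
#' recorded in `$meta` so a table set is reproducible from its metadata.
#'
#' @param mortality_anchor_age,mortality_anchor,mortality_slope Mortality
#'   generator settings.
#' @param incidence_anchor_age,incidence_anchor,incidence_slope Incidence
#'   generator settings.
#' @param rr_smoker Current-smoker RR, sexes combined.
#' @param rr_ex_anchor,rr_ex_anchor_ysq,rr_floor Ex-smoker RR settings.
#' @param sex_rr_multiplier Named vector, multipliers on the RR excess for
#'   `male` and `female`; male must be >= female.
#' @param s1,s5 All-stage cumulative survival anchors.
#' @param p_early Early-stage fraction used to derive stage-specific survival.
#' @param early_hazard_factor See [stage_survival()].
#' @param ages Ages covered by the age-indexed tables.
#' @return An object of class `"epi_tables"`.
#' @export
#' @examples
#' epi <- epi_tables()
#' epi$mortality$value[epi$mortality$age == 65]
epi_tables <- function(mortality_anchor_age = 65, mortality_anchor = 0.00936,
                       mortality_slope = 0.09,
                       incidence_anchor_age = 65, incidence_anchor = 0.0018024,
                       incidence_slope = 0.08,
                       rr_smoker = 6.609, rr_ex_anchor = 4.75,
                       rr_ex_anchor_ysq = 3, rr_floor = 1.5,
                       sex_rr_multiplier = c(male = 1.2, female = 0.8),
                       s1 = 0.36, s5 = 0.12, p_early = 0.20,
                       early_hazard_factor = 0.5, ages = 30:100) {
  if (sex_rr_multiplier[["male"]] < sex_rr_multiplier[["female"]]) {
    stop("sex_rr_multiplier: male must be >= female", call. = FALSE)
  }
  rr_cs <- c(
    both = rr_smoker,
    male = 1 + sex_rr_multiplier[["male"]] * (rr_smoker - 1),
    female = 1 + sex_rr_multiplier[["female"]] * (rr_smoker - 1)
  )
  epi <- new_epi_tables(
    mortality = make_mortality_table(mortality_anchor_age, mortality_anchor,
                                     mortality_slope, ages),
    incidence = make_incidence_table(incidence_anchor_age, incidence_anchor,
                                     incidence_slope, ages),
    rr_current_smoker = rr_cs,
    rr_ex_smoker = make_ex_smoker_rr(rr_smoker, rr_ex_anchor,
                                     rr_ex_anchor_ysq, rr_floor),
    lc_survival = stage_survival(lc_survival_curve(s1, s5), p_early,
                                 early_hazard_factor),
    meta = list(
      mortality = list(anchor_age = mortality_anchor_age,
                       anchor_rate = mortality_anchor, slope = mortality_slope),
      incidence = list(anchor_age = incidence_anchor_age,
                       anchor_rate = incidence_anchor, slope = incidence_slope),
      rr = list(smoker = rr_smoker, ex_anchor = rr_ex_anchor,
                ex_anchor_ysq = rr_ex_anchor_ysq, floor = rr_floor,
                sex_multiplier = as.list(sex_rr_multiplier)),
      survival = list(s1 = s1, s5 = s5, p_early = p_early,
                      early_hazard_factor = early_hazard_factor)
    )
  )
  validate_epi(epi)
  epi
}

#' Validate an epidemiological table set
#'
#' Checks probabilities lie in `[0, 1]`, ex-smoker RRs never exceed the
#' current-smoker RR and never fall below 1, survival is strictly decreasing,
#' and smoker risk (incidence x RR) stays below 1 at every tabulated age.
#'
#' @param epi An `epi_tables` object.
#' @return The object, invisibly; errors name the failing table.
#' @export
validate_epi <- function(epi) {
  fail <- function(tbl, msg) {
    stop("invalid epi tables: ", tbl, " ", msg, call. = FALSE)
  }
  for (tbl in c("mortality", "incidence")) {
    v <- epi[[tbl]]$value
    if (any(v < 0 | v > 1)) fail(tbl, "has probabilities outside [0, 1]")
  }
  rr_max <- max(epi$rr_current_smoker)
  if (any(epi$rr_ex_smoker$value > max(epi$rr_current_smoker) + 1e-12)) {
    fail("rr_ex_smoker", "exceeds the current-smoker RR")
  }
  if (any(epi$rr_ex_smoker$value < 1)) {
    fail("rr_ex_smoker", "falls below 1 (ex-smoker risk stays elevated)")
  }
  mono <- epi$rr_ex_smoker |>
    dplyr::group_by(.data$age_group) |>
    dplyr::summarise(ok = all(diff(.data$value) <= 1e-12), .groups = "drop")
  if (!all(mono$ok)) fail("rr_ex_smoker", "is not non-increasing in years since quit")
  surv <- epi$lc_survival |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(ok = all(diff(.data$survival) < 0) &&
                       all(.data$survival > 0 & .data$survival <= 1),
                     .groups = "drop")
  if (!all(surv$ok)) fail("lc_survival", "must be strictly decreasing in (0, 1]")
  risk <- epi$incidence$value * rr_max
  if (any(risk > 1)) fail("incidence", "x RR exceeds 1 at some age")
  invisible(epi)
}

#' @export
print.epi_tables <- function(x, ...) {
  cat("<epi_tables>\n")
  cat("  ages ", min(x$mortality$age), "-", max(x$mortality$age), "\n", sep = "")
  cat("  current-smoker RR: ",
      paste(names(x$rr_current_smoker),
            sprintf("%.3f", x$rr_current_smoker), collapse = ", "), "\n", sep = "")
  cat("  survival anchors: S(1) = ",
      x$lc_survival$survival[x$lc_survival$stage == "all" & x$lc_survival$year == 1],
      ", S(5) = ",
      x$lc_survival$survival[x$lc_survival$stage == "all" & x$lc_survival$year == 5],
      "\n", sep = "")
  invisible(x)
}

#' Write the sidecar CSV tables for an epi set
#'
#' Emits `mortality.csv`, `incidence.csv`, `rr_ex_smoker.csv` and
#' `lc_survival.csv` in the layout [load_config()] reads back.
#'
#' @param epi An `epi_tables` object.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_epi_csvs <- function(epi, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(epi$mortality, file.path(dir, "mortality.csv"))
  readr::write_csv(epi$incidence, file.path(dir, "incidence.csv"))
  readr::write_csv(epi$rr_ex_smoker, file.path(dir, "rr_ex_smoker.csv"))
  readr::write_csv(epi$lc_survival, file.path(dir, "lc_survival.csv"))
  invisible(dir)
}

# Look up an age-indexed value, preferring sex-specific rows when present and
# falling back to the combined table.
epi_lookup <- function(tbl, ages, sex) {
  keep <- tbl$sex == sex
  if (!any(keep)) keep <- tbl$sex == "both"
  idx <- match(ages, tbl$age[keep])
  if (anyNA(idx)) {
    stop("age ", paste(ages[is.na(idx)], collapse = ", "),
         " outside table coverage", call. = FALSE)
  }
  tbl$value[keep][idx]
}

# Ex-smoker RR for given ages and matching years-since-quit, with the sex
# excess factor applied.
rr_ex_lookup <- function(epi, ages, ysq, sex) {
  groups <- pmin(pmax(30, 5 * floor(ages / 5)), max(epi$rr_ex_smoker$age_group))
  ysq <- pmin(ysq, max(epi$rr_ex_smoker$years_since_quit))
  key <- groups * 1000 + ysq
  tab_key <- epi$rr_ex_smoker$age_group * 1000 + epi$rr_ex_smoker$years_since_quit
  v <- epi$rr_ex_smoker$value[match(key, tab_key)]
  if (anyNA(v)) stop("rr_ex_smoker lookup outside table coverage", call. = FALSE)
  if (sex != "both") {
    f <- (epi$rr_current_smoker[[sex]] - 1) / (epi$rr_current_smoker[["both"]] - 1)
    v <- 1 + f * (v - 1)
  }
  v
}
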