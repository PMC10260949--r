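#' Relative risks of CHD per daily SSB serving
#'
#' The mortality engine uses two age-specific relative risks per
#' serving/day of SSB: a BMI-adjusted RR (the direct effect of SSB on
#' CHD, independent of body mass) and a BMI-mediated RR (the effect
#' operating through raised BMI, applied in proportion to overweight
#' prevalence). Both are per-serving log-linear risks.
#'
#' @param df data.frame with columns `age_group`, `rr_adjusted`,
#'   `rr_mediated`, one row per age group (all seven required).
#' @return object of class `relative_risk_set`.
#' @export
relative_risk_set <- function(df) {
  need <- c("age_group", "rr_adjusted", "rr_mediated")
  if (!all(need %in% names(df))) {
    stop("relative risk table needs columns: ", paste(need, collapse = ", "))
  }
  df <- as.data.frame(df)[need]
  if (!setequal(df$age_group, age_groups()) ||
      anyDuplicated(df$age_group)) {
    stop("relative risk table must have exactly one row per age group")
  }
  if (any(df$rr_adjusted <= 0) || any(df$rr_mediated <= 0)) {
    stop("relative risks must be positive")
  }
  df <- df[match(age_groups(), df$age_group), ]
  rownames(df) <- NULL
  structure(df, class = c("relative_risk_set", "data.frame"))
}

#' Default per-serving relative risks
#'
#' Calibrated defaults, declining with age as excess relative risks of
#' diet-related exposures typically do. They are in the range reported
#' by pooled cohort analyses of SSB intake and incident CHD (of the
#' order of 1.1-1.2 per daily serving in middle age) but are this
#' package's own calibration, not values taken from any single study.
#'
#' @return a [relative_risk_set()].
#' @export
default_relative_risks <- function() {
  relative_risk_set(data.frame(
    age_group = age_groups(),
    rr_adjusted = c(1.20, 1.18, 1.16, 1.14, 1.12, 1.10, 1.08),
    rr_mediated = c(1.10, 1.09, 1.08, 1.07, 1.06, 1.05, 1.04)))
}

#' Potential impact fraction of a serving reduction on CHD mortality
#'
#' The proportional reduction in CHD deaths from reducing SSB intake by
#' `servings_change` servings/day is computed as the sum of a
#' BMI-adjusted and a BMI-mediated potential impact fraction:
#' \deqn{PIF = (1 - RR_{adj}^{-\Delta s}) +
#'       (1 - RR_{med}^{-\Delta s}) \, p_{ow}}
#' where \eqn{p_{ow}} is the stratum's overweight prevalence, so the
#' BMI-mediated pathway only operates in the overweight fraction of the
#' population. Because SSB intake is assumed not to alter case fatality,
#' the incidence PIF applies directly to mortality. The result is
#' clamped to [0, 1).
#'
#' @param servings_change reduction in servings/day (positive =
#'   reduction); vectorised.
#' @param rr a [relative_risk_set()].
#' @param age_group age-group label(s), recycled against
#'   `servings_change`.
#' @param overweight_prevalence fraction(s) in [0, 1].
#' @return fraction(s) of the stratum's CHD deaths averted.
#' @export
mortality_reduction_fraction <- function(servings_change, rr, age_group,
                                         overweight_prevalence) {
  stopifnot(inherits(rr, "relative_risk_set"))
  idx <- match(age_group, rr$age_group)
  if (anyNA(idx)) {
    stop("no relative risks for age group(s): ",
         paste(unique(age_group[is.na(idx)]), collapse = ", "))
  }
  if (any(overweight_prevalence < 0 | overweight_prevalence > 1)) {
    stop("overweight_prevalence must be in [0, 1]")
  }
  pif_adj <- 1 - rr$rr_adjusted[idx]^(-servings_change)
  pif_med <- 1 - rr$rr_mediated[idx]^(-servings_change)
  pmin(pmax(pif_adj + pif_med * overweight_prevalence, 0), 1 - 1e-12)
}

#' Deaths prevented or postponed in a stratum
#'
#' @param stratum_deaths baseline CHD deaths in the stratum.
#' @param reduction_fraction fraction from
#'   [mortality_reduction_fraction()].
#' @return fractional deaths prevented or postponed (rounding is left to
#'   report time).
#' @export
deaths_prevented <- function(stratum_deaths, reduction_fraction) {
  stratum_deaths * reduction_fraction
}

#' Life-years gained from prevented deaths
#'
#' Each death prevented gains the median survival of the subgroup the
#' decedent belonged to: diagnosed CHD, undiagnosed CHD or no prior CHD.
#' LYG is DPP times the proportion-weighted mean median survival.
#'
#' @param dpp deaths prevented or postponed (vectorised).
#' @param proportions matrix/data.frame with columns `p_diag`,
#'   `p_undiag`, `p_none` (rows matching `dpp`), summing to 1 per row.
#' @param survival matrix/data.frame with columns `surv_diag`,
#'   `surv_undiag`, `surv_none`, years.
#' @return life-years gained.
#' @export
life_years_gained <- function(dpp, proportions, survival) {
  p <- as.matrix(as.data.frame(proportions)[c("p_diag", "p_undiag", "p_none")])
  s <- as.matrix(as.data.frame(survival)[c("surv_diag", "surv_undiag",
                                           "surv_none")])
  if (any(abs(rowSums(p) - 1) > .share_tol)) {
    stop("CHD-status proportions must sum to 1")
  }
  dpp * rowSums(p * s)
}

#' Run one policy scenario against a baseline
#'
#' Chains the full model: trade regime to sugar price change, levy plus
#' sugar cost to SSB production cost, pass-through to consumer price
#' change, SEC-differentiated demand response to intake change, and the
#' potential impact fraction to deaths prevented or postponed (DPP) and
#' life-years gained (LYG), per stratum and aggregated.
#'
#' @param baseline a [baseline_table()].
#' @param scenario a [scenario()].
#' @return object of class `impact_result`: a list with elements
#'   `strata` (per-stratum data.frame including intake changes, DPP,
#'   LYG), `total` (named vector: dpp, lyg), `by_age` (DPP/LYG and DPP
#'   as a percent of baseline deaths per age group), `by_quintile`
#'   (DPP/LYG per IMD quintile), `prices` (sugar price change GBP/t,
#'   cost change GBP/l, relative consumer price change), `intake`
#'   (overall intake-weighted relative change), plus the scenario label
#'   and pass-through.
#' @export
run_scenario <- function(baseline, scenario) {
  stopifnot(inherits(scenario, "scenario"))
  baseline <- validate_baseline(baseline)

  dp_sugar <- if (is.null(scenario$trade)) 0 else
    sugar_price_change(scenario$trade)
  levy_rate <- if (is.null(scenario$levy)) 0 else
    pooled_levy_rate(scenario$levy)
  cost <- production_cost_change(dp_sugar, scenario$price, levy_rate)
  dprice <- consumer_price_change(cost, scenario$price)

  chg <- apply_to_baseline(dprice, scenario$effect, baseline,
                           scenario$serving_size)
  frac <- mortality_reduction_fraction(
    pmax(-chg$servings_change, 0), scenario$rr,
    baseline$age_group, baseline$overweight)
  dpp <- deaths_prevented(baseline$deaths, frac)
  lyg <- life_years_gained(dpp, baseline, baseline)

  strata <- data.frame(
    baseline[, c("age_group", "sex", "imd_quintile", "deaths",
                 "population", "intake")],
    relative_change = chg$relative_change,
    absolute_change = chg$absolute_change,
    servings_change = chg$servings_change,
    reduction_fraction = frac,
    dpp = dpp, lyg = lyg)

  by_age <- aggregate_impact(strata, "age_group", age_groups())
  by_age$dpp_pct_of_deaths <- 100 * by_age$dpp / by_age$deaths
  by_q <- aggregate_impact(strata, "imd_quintile", imd_quintiles())

  structure(list(
    label = scenario$label,
    pass_through = scenario$price$pass_through,
    strata = strata,
    total = c(dpp = sum(dpp), lyg = sum(lyg)),
    by_age = by_age,
    by_quintile = by_q,
    prices = c(sugar_price_change = dp_sugar,
               cost_change = cost,
               consumer_price_change = dprice),
    intake = c(overall_relative_change = attr(chg, "overall"))),
    class = "impact_result")
}

aggregate_impact <- function(strata, key, levels) {
  out <- data.frame(key = levels)
  names(out) <- key
  idx <- match(strata[[key]], levels)
  for (v in c("deaths", "dpp", "lyg")) {
    out[[v]] <- as.numeric(tapply(strata[[v]], factor(idx, seq_along(levels)),
                                  sum))
  }
  out
}

#' @export
print.impact_result <- function(x, ...) {
  cat(sprintf("Scenario '%s' (pass-through %.0f %%)\n",
              x$label, 100 * x$pass_through))
  cat(sprintf("  sugar price change:    %8.2f GBP/t\n",
              x$prices[["sugar_price_change"]]))
  cat(sprintf("  production cost change:%8.4f GBP/l\n",
              x$prices[["cost_change"]]))
  cat(sprintf("  consumer price change: %8.1f %%\n",
              100 * x$prices[["consumer_price_change"]]))
  cat(sprintf("  overall intake change: %8.1f %%\n",
              100 * x$intake[["overall_relative_change"]]))
  cat(sprintf("  total DPP: %.0f   total LYG: %.0f\n",
              x$total[["dpp"]], x$total[["lyg"]]))
  invisible(x)
}
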