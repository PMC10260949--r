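#' Socio-economically differentiated price effect on SSB intake
#'
#' The demand response is anchored on a meta-analytic estimate that a
#' 10 % SSB price increase reduces SSB consumption by 6.7 %. Price
#' responsiveness differs by socio-economic circumstance (SEC): the
#' high-deprivation group is taken to be 65 % more responsive than the
#' low-deprivation group, so the multiplier ratio high/low defaults to
#' 1.65. The effect is applied linearly in the price change (a 38 %
#' price rise gives 3.8 times the per-10 % effect), capped so intake
#' cannot fall below zero.
#'
#' `sec_multipliers` may be NULL, in which case [apply_to_baseline()]
#' calibrates them against the baseline it is given (see
#' [calibrate_sec_multipliers()]); functions that have no baseline in
#' scope use the equal-weight calibration (0.7547, 1, 1.2453).
#'
#' @param base_effect percent intake decrease per 10 % price increase
#'   (default 6.7).
#' @param sec_multipliers named numeric vector over SEC groups
#'   ("low", "mid", "high" deprivation) multiplying `base_effect`, or
#'   NULL to calibrate from the baseline at application time.
#' @param sec_grouping quintile-to-group map, see
#'   [default_sec_grouping()].
#' @param responsiveness_ratio required ratio max/min of the multipliers
#'   (default 1.65); checked when multipliers are supplied, used as the
#'   calibration constraint when they are not.
#' @return object of class `price_effect`.
#' @export
price_effect <- function(base_effect = 6.7,
                         sec_multipliers = NULL,
                         sec_grouping = default_sec_grouping(),
                         responsiveness_ratio = 1.65) {
  if (base_effect <= 0) stop("base_effect must be positive")
  if (!is.null(sec_multipliers)) {
    if (any(sec_multipliers <= 0)) stop("sec_multipliers must be positive")
    groups <- unique(unname(sec_grouping))
    if (!all(groups %in% names(sec_multipliers))) {
      stop("sec_multipliers must name every SEC group: ",
           paste(groups, collapse = ", "))
    }
    ratio <- max(sec_multipliers) / min(sec_multipliers)
    if (abs(ratio - responsiveness_ratio) > 1e-6) {
      stop("max/min of sec_multipliers must equal the responsiveness ",
           "ratio (", responsiveness_ratio, "); got ", format(ratio))
    }
  }
  structure(list(base_effect = base_effect,
                 sec_multipliers = sec_multipliers,
                 sec_grouping = sec_grouping,
                 responsiveness_ratio = responsiveness_ratio),
            class = "price_effect")
}

# multipliers with ratio r and unit mean under equal group weights
equal_weight_multipliers <- function(ratio = 1.65) {
  m <- c(low = 1, mid = (1 + ratio) / 2, high = ratio)
  m / mean(m)
}

#' Calibrate SEC multipliers against a baseline
#'
#' Chooses price-effect multipliers for the three SEC groups such that
#' (a) the high/low-deprivation ratio equals `ratio`, (b) the middle
#' group sits at the arithmetic midpoint, and (c) the population-intake
#' weighted mean multiplier is exactly 1 -- so the population-average
#' demand response equals the base effect under the given baseline.
#'
#' @param baseline a baseline table (see [baseline_table()]).
#' @param ratio high/low responsiveness ratio (default 1.65).
#' @param sec_grouping quintile-to-group map.
#' @return named numeric vector of multipliers ("low", "mid", "high").
#' @export
calibrate_sec_multipliers <- function(baseline, ratio = 1.65,
                                      sec_grouping = default_sec_grouping()) {
  baseline <- validate_baseline(baseline)
  grp <- sec_group(baseline$imd_quintile, sec_grouping)
  w <- baseline$population * baseline$intake
  wg <- vapply(c("low", "mid", "high"),
               function(g) sum(w[grp == g]), numeric(1))
  wg <- wg / sum(wg)
  shape <- c(low = 1, mid = (1 + ratio) / 2, high = ratio)
  shape / sum(wg * shape)
}

resolve_multipliers <- function(effect, baseline = NULL) {
  if (!is.null(effect$sec_multipliers)) return(effect$sec_multipliers)
  if (is.null(baseline)) {
    return(equal_weight_multipliers(effect$responsiveness_ratio))
  }
  calibrate_sec_multipliers(baseline, effect$responsiveness_ratio,
                            effect$sec_grouping)
}

#' Relative intake change for a given price change and quintile
#'
#' Linear scaling of the per-10 % price effect:
#' `-(base_effect * multiplier / 10) * price_change`, with `price_change`
#' a fraction (0.10 = +10 %). Capped at -1 so intake cannot go negative.
#'
#' @param price_change relative consumer price change (fraction, >= -1).
#' @param effect a [price_effect()].
#' @param quintile IMD quintile(s) in 1:5 (vectorised).
#' @param baseline optional baseline table used to calibrate multipliers
#'   when `effect$sec_multipliers` is NULL.
#' @return relative intake change (negative = reduction), same length as
#'   `quintile` (or `price_change` if longer).
#' @export
#' @examples
#' relative_intake_change(0.10, price_effect(sec_multipliers =
#'   c(low = 1, mid = 1, high = 1), responsiveness_ratio = 1), 3) # -0.067
relative_intake_change <- function(price_change, effect, quintile,
                                   baseline = NULL) {
  stopifnot(inherits(effect, "price_effect"))
  if (any(price_change < -1)) stop("price_change must be >= -1")
  mult <- resolve_multipliers(effect, baseline)
  grp <- sec_group(quintile, effect$sec_grouping)
  rel <- -(effect$base_effect * mult[grp] / 10) * price_change
  unname(pmax(rel, -1))
}

#' Apply a price change to a baseline table
#'
#' Computes, for every stratum, the relative intake change from
#' [relative_intake_change()], the absolute change in g/day against the
#' stratum's baseline intake, and the change in servings/day at the given
#' serving size. The attribute `overall` carries the population-intake
#' weighted mean relative change -- the "overall population" reduction.
#'
#' @param price_change relative consumer price change (scalar fraction).
#' @param effect a [price_effect()].
#' @param baseline a baseline table (see [baseline_table()]).
#' @param serving_size grams of SSB per serving (default 250, roughly a
#'   250 ml glass).
#' @return data.frame with the stratum keys and columns
#'   `relative_change`, `absolute_change` (g/day, negative = reduction)
#'   and `servings_change` (servings/day); attribute `overall` holds the
#'   intake-weighted mean relative change.
#' @export
apply_to_baseline <- function(price_change, effect, baseline,
                              serving_size = 250) {
  stopifnot(inherits(effect, "price_effect"), length(price_change) == 1)
  if (serving_size <= 0) stop("serving_size must be positive")
  baseline <- validate_baseline(baseline)
  rel <- relative_intake_change(price_change, effect,
                                baseline$imd_quintile, baseline)
  abs_chg <- rel * baseline$intake
  out <- data.frame(baseline[, c("age_group", "sex", "imd_quintile")],
                    relative_change = rel,
                    absolute_change = abs_chg,
                    servings_change = abs_chg / serving_size)
  w <- baseline$population * baseline$intake
  attr(out, "overall") <- if (sum(w) > 0) sum(w * rel) / sum(w) else 0
  out
}
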