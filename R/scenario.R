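#' Assemble a policy scenario
#'
#' A scenario bundles everything that defines one model run: the levy
#' (or none), the trade regime (or none), market price assumptions
#' including the pass-through rate, the demand-side price effect, the
#' serving size used to convert grams to servings, and the relative
#' risks.
#'
#' @param label free-text scenario label.
#' @param levy a [levy_spec()] or NULL for a levy-free scenario.
#' @param trade a [trade_scenario()], the name of a packaged one
#'   ("none", "soft", "hard"), or NULL (same as "none").
#' @param price a [price_assumptions()].
#' @param effect a [price_effect()].
#' @param serving_size grams per serving (default 250).
#' @param rr a [relative_risk_set()].
#' @return object of class `scenario`.
#' @export
scenario <- function(label,
                     levy = levy_spec(),
                     trade = NULL,
                     price = price_assumptions(),
                     effect = price_effect(),
                     serving_size = 250,
                     rr = default_relative_risks()) {
  if (is.character(trade)) trade <- default_trade_scenario(trade)
  if (!is.null(trade) && !inherits(trade, "trade_scenario")) {
    stop("trade must be a trade_scenario, a packaged scenario name, or NULL")
  }
  if (!is.null(levy) && !inherits(levy, "levy_spec")) {
    stop("levy must be a levy_spec or NULL")
  }
  stopifnot(inherits(price, "price_assumptions"),
            inherits(effect, "price_effect"),
            inherits(rr, "relative_risk_set"))
  if (serving_size <= 0) stop("serving_size must be positive")
  structure(list(label = label, levy = levy, trade = trade, price = price,
                 effect = effect, serving_size = serving_size, rr = rr),
            class = "scenario")
}

#' The three standard policy scenarios
#'
#' "levy" (the two-rate levy with no trade change), "levy+soft" and
#' "levy+hard" (the levy plus the corresponding Brexit sugar-price
#' increment), all at the given pass-through rate.
#'
#' @param pass_through pass-through rate (default 1).
#' @param ... further arguments passed to [scenario()] (e.g. `effect`,
#'   `rr`, `serving_size`).
#' @return named list of three [scenario()] objects.
#' @export
standard_scenarios <- function(pass_through = 1, ...) {
  pa <- price_assumptions(pass_through = pass_through)
  list(
    "levy"      = scenario("levy", trade = "none", price = pa, ...),
    "levy+soft" = scenario("levy+soft", trade = "soft", price = pa, ...),
    "levy+hard" = scenario("levy+hard", trade = "hard", price = pa, ...))
}

#' Read a scenario configuration file
#'
#' The configuration is a YAML document with optional top-level sections
#' `levy`, `trade`, `price`, `effect`, `rr`, `serving_size`, `psa` and a
#' `scenarios` list; anything omitted falls back to the packaged
#' defaults, and every resolved default is recorded in the returned
#' object so a run manifest can echo it. See
#' `system.file("extdata", "standard_scenarios.yaml", package =
#' "ssbimpact")` for a complete example reproducing the standard
#' three-scenario analysis.
#'
#' @param path path to a YAML config file.
#' @return list with elements `scenarios` (named list of [scenario()]
#'   objects, one per configured scenario x pass-through), `psa`
#'   (distribution settings, iterations and seed, or NULL) and
#'   `resolved` (a flat named list of every value used, defaults
#'   included).
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  build_scenarios_from_config(cfg)
}

config_error <- function(field, msg) {
  stop("config field '", field, "': ", msg, call. = FALSE)
}

build_scenarios_from_config <- function(cfg) {
  levy <- if (is.null(cfg$levy)) levy_spec() else {
    br <- unlist(cfg$levy$band_rates)
    bs <- unlist(cfg$levy$band_sales_shares)
    if (is.null(br) || is.null(bs)) {
      config_error("levy", "needs band_rates and band_sales_shares maps")
    }
    levy_spec(br, bs)
  }
  price <- price_assumptions(
    sugar_content = cfg$price$sugar_content %||% 93,
    baseline_price = cfg$price$baseline_price %||% 0.61,
    pass_through = 1)
  effect <- price_effect(
    base_effect = cfg$effect$base_effect %||% 6.7,
    sec_multipliers = if (!is.null(cfg$effect$sec_multipliers))
      unlist(cfg$effect$sec_multipliers),
    responsiveness_ratio = cfg$effect$responsiveness_ratio %||% 1.65)
  rr <- if (is.null(cfg$rr)) default_relative_risks() else {
    relative_risk_set(data.frame(
      age_group = vapply(cfg$rr, `[[`, "", "age_group"),
      rr_adjusted = vapply(cfg$rr, function(r) as.numeric(r$rr_adjusted), 0),
      rr_mediated = vapply(cfg$rr, function(r) as.numeric(r$rr_mediated), 0)))
  }
  serving <- cfg$serving_size %||% 250
  pass_throughs <- as.numeric(cfg$pass_throughs %||% c(0.8, 1.0, 1.2))

  scen_defs <- cfg$scenarios %||% list(
    list(label = "levy", trade = "none"),
    list(label = "levy+soft", trade = "soft"),
    list(label = "levy+hard", trade = "hard"))

  scenarios <- list()
  for (sd in scen_defs) {
    if (is.null(sd$label)) config_error("scenarios", "each needs a label")
    trade <- sd$trade %||% "none"
    if (is.list(trade)) {
      trade <- trade_scenario(
        import_share_of_supply = trade$import_share_of_supply,
        segment_shares = unlist(trade$segment_shares),
        tariff_change = unlist(trade$tariff_change),
        facilitation_cost = unlist(trade$facilitation_cost),
        exchange_rate = trade$exchange_rate %||% 1,
        currency = trade$currency %||% "GBP",
        label = sd$label)
    }
    this_levy <- if (isTRUE(sd$no_levy)) NULL else levy
    for (pt in pass_throughs) {
      pa <- price_assumptions(price$sugar_content, price$baseline_price, pt)
      key <- sprintf("%s@%g", sd$label, pt)
      scenarios[[key]] <- scenario(sd$label, levy = this_levy,
                                   trade = trade, price = pa,
                                   effect = effect,
                                   serving_size = serving, rr = rr)
    }
  }

  psa <- if (!is.null(cfg$psa)) {
    list(iterations = cfg$psa$iterations %||% 10000L,
         seed = cfg$psa$seed %||% 1L,
         distributions = if (is.null(cfg$psa$distributions))
           default_psa_distributions()
         else psa_distributions_from_config(cfg$psa$distributions))
  }

  resolved <- list(
    band_rates = levy$band_rates,
    band_sales_shares = levy$band_sales_shares,
    pooled_levy_rate = pooled_levy_rate(levy),
    sugar_content = price$sugar_content,
    baseline_price = price$baseline_price,
    pass_throughs = pass_throughs,
    base_effect = effect$base_effect,
    responsiveness_ratio = effect$responsiveness_ratio,
    serving_size = serving,
    psa_iterations = psa$iterations,
    psa_seed = psa$seed)

  list(scenarios = scenarios, psa = psa, resolved = resolved)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
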