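#' Define a post-Brexit sugar trade scenario
#'
#' A trade scenario describes how a change in the UK's trading regime
#' feeds through to the wholesale price of sugar. Imports are split into
#' three segments -- EU, third-country preferential and third-country
#' non-preferential -- each carrying a change in applied tariff and an
#' added trade-facilitation (border friction) cost, in currency per tonne
#' of sugar. The scenario also records what share of total sugar supply
#' is imported, since only the imported share is assumed to re-price.
#'
#' @param import_share_of_supply fraction of total sugar supply that is
#'   imported (default 0.64, the UK position in 2015).
#' @param segment_shares named numeric vector of import-segment shares
#'   (must sum to 1). Default: 53 % EU; of the remaining 47 % third-country
#'   imports, 94 % enter under preferential agreements.
#' @param tariff_change named numeric vector, currency/tonne: post- minus
#'   pre-Brexit applied tariff per segment.
#' @param facilitation_cost named numeric vector, currency/tonne of added
#'   border friction per segment.
#' @param exchange_rate pounds per unit of `currency`; applied only when
#'   `currency` is not "GBP".
#' @param currency "GBP" or "EUR" -- the denomination of the tariff and
#'   facilitation inputs.
#' @param label free-text label ("none", "soft", "hard", or custom).
#' @return object of class `trade_scenario`.
#' @seealso [default_trade_scenario()] for the packaged scenarios,
#'   [sugar_price_change()] for the price arithmetic.
#' @export
trade_scenario <- function(import_share_of_supply,
                           segment_shares,
                           tariff_change,
                           facilitation_cost,
                           exchange_rate = 1,
                           currency = c("GBP", "EUR"),
                           label = "custom") {
  currency <- match.arg(currency)
  if (!is.numeric(import_share_of_supply) ||
      import_share_of_supply < 0 || import_share_of_supply > 1) {
    stop("import_share_of_supply must be a fraction in [0, 1]")
  }
  check_shares(segment_shares, "segment_shares")
  segs <- names(segment_shares)
  if (is.null(segs) || any(segs == "")) stop("segment_shares must be named")
  for (v in list(tariff_change = tariff_change,
                 facilitation_cost = facilitation_cost)) {
    if (!setequal(names(v), segs)) {
      stop("tariff_change and facilitation_cost must be named for the same ",
           "segments as segment_shares")
    }
  }
  if (!is.numeric(exchange_rate) || exchange_rate <= 0) {
    stop("exchange_rate must be positive")
  }
  structure(
    list(import_share_of_supply = import_share_of_supply,
         segment_shares = segment_shares,
         tariff_change = tariff_change[segs],
         facilitation_cost = facilitation_cost[segs],
         exchange_rate = exchange_rate,
         currency = currency,
         label = label),
    class = "trade_scenario")
}

#' Packaged trade scenarios
#'
#' Three named scenarios are shipped:
#' \describe{
#'   \item{"none"}{no regime change; the sugar price change is exactly 0.}
#'   \item{"soft"}{a zero-duty free-trade agreement with the EU, WTO
#'     tariffs applied to all third countries (including those that
#'     previously held EU preferential access), plus a small facilitation
#'     cost on all imports. Yields a sugar price increase of 92 GBP/t.}
#'   \item{"hard"}{the WTO default position: most-favoured-nation tariffs
#'     on every import segment and a larger facilitation cost. Yields
#'     203 GBP/t.}
#' }
#' The import shares (64 % of supply imported; 53 % of imports from the
#' EU; 94 % of third-country imports preferential) are fixed at their
#' published 2015 values. The per-segment tariff schedule behind the two
#' headline price changes is not published at segment resolution, so the
#' packaged WTO tariff (400 EUR/t) and facilitation costs are calibrated
#' so the scenarios reproduce the 92 and 203 GBP/t end-points exactly at
#' the default exchange rate of 0.80 GBP/EUR; all of these are editable.
#'
#' @param label one of "none", "soft", "hard".
#' @return a [trade_scenario()].
#' @export
#' @examples
#' sugar_price_change(default_trade_scenario("soft")) # 92
default_trade_scenario <- function(label = c("none", "soft", "hard")) {
  label <- match.arg(label)
  segs <- c(eu = 0.53,
            third_preferential = 0.47 * 0.94,
            third_non_preferential = 0.47 * 0.06)
  zero <- c(eu = 0, third_preferential = 0, third_non_preferential = 0)
  wto <- 400  # EUR/t most-favoured-nation sugar tariff (calibrated)
  switch(label,
    none = trade_scenario(0.64, segs, zero, zero,
                          exchange_rate = 1, currency = "GBP",
                          label = "none"),
    soft = trade_scenario(
      0.64, segs,
      tariff_change = c(eu = 0, third_preferential = wto,
                        third_non_preferential = 0),
      facilitation_cost = zero + 2.9675,
      exchange_rate = 0.80, currency = "EUR", label = "soft"),
    hard = trade_scenario(
      0.64, segs,
      tariff_change = c(eu = wto, third_preferential = wto,
                        third_non_preferential = 0),
      facilitation_cost = zero + 7.764375,
      exchange_rate = 0.80, currency = "EUR", label = "hard"))
}

#' Sugar price change implied by a trade scenario
#'
#' Computes the share-weighted change in the wholesale sugar price:
#' the import share of supply times the segment-share-weighted sum of
#' tariff changes and facilitation costs, converted to pounds when the
#' scenario is euro-denominated. Only the imported share of supply is
#' assumed to re-price; the domestic production price response is not
#' modelled.
#'
#' @param scenario a [trade_scenario()].
#' @return sugar price change in GBP per tonne (0 for the "none"
#'   scenario).
#' @export
sugar_price_change <- function(scenario) {
  if (!inherits(scenario, "trade_scenario")) {
    stop("scenario must be a trade_scenario object")
  }
  per_tonne <- sum(scenario$segment_shares *
                     (scenario$tariff_change + scenario$facilitation_cost))
  fx <- if (scenario$currency == "EUR") scenario$exchange_rate else 1
  scenario$import_share_of_supply * per_tonne * fx
}

#' @export
print.trade_scenario <- function(x, ...) {
  cat("Trade scenario:", x$label, "\n")
  cat("  imported share of sugar supply:", x$import_share_of_supply, "\n")
  cat("  segments (share / tariff change / facilitation, ",
      x$currency, "/t):\n", sep = "")
  for (s in names(x$segment_shares)) {
    cat(sprintf("    %-24s %5.3f / %8.3f / %8.3f\n", s,
                x$segment_shares[[s]], x$tariff_change[[s]],
                x$facilitation_cost[[s]]))
  }
  cat(sprintf("  sugar price change: %.2f GBP/t\n", sugar_price_change(x)))
  invisible(x)
}
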