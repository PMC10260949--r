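#' Specify a banded SSB levy
#'
#' The UK soft drinks industry levy is a two-rate levy on sugar-sweetened
#' beverages: 18 p/l on drinks containing 5-8 g sugar per 100 ml and
#' 24 p/l above 8 g/100 ml (drinks under 5 g/100 ml are zero-rated and
#' excluded from the default bands; they can be represented with a
#' rate-0 band if needed). Band sales shares are the fractions of levied
#' SSB sales volume falling in each band, used to pool the bands into a
#' single average rate.
#'
#' @param band_rates named numeric vector, levy in GBP per litre per band.
#' @param band_sales_shares named numeric vector of sales-volume shares
#'   (same names, summing to 1). The packaged default (1/6 mid, 5/6 high)
#'   reproduces the 23 p/l pooled rate implied by 2017 sales data.
#' @return object of class `levy_spec`.
#' @export
levy_spec <- function(band_rates = c(mid = 0.18, high = 0.24),
                      band_sales_shares = c(mid = 1 / 6, high = 5 / 6)) {
  if (any(band_rates < 0)) stop("band_rates must be non-negative")
  check_shares(band_sales_shares, "band_sales_shares")
  if (!setequal(names(band_rates), names(band_sales_shares))) {
    stop("band_rates and band_sales_shares must cover the same bands")
  }
  structure(list(band_rates = band_rates,
                 band_sales_shares = band_sales_shares[names(band_rates)]),
            class = "levy_spec")
}

#' Pooled single-rate levy equivalent
#'
#' Sales-weighted average of the band rates: the per-litre cost the levy
#' imposes on the industry across the levied market.
#'
#' @param levy a [levy_spec()].
#' @return pooled levy rate in GBP per litre (0.23 for the defaults).
#' @export
#' @examples
#' pooled_levy_rate(levy_spec()) # 0.23
pooled_levy_rate <- function(levy) {
  if (!inherits(levy, "levy_spec")) stop("levy must be a levy_spec object")
  sum(levy$band_rates * levy$band_sales_shares)
}

#' Market-level price assumptions
#'
#' @param sugar_content mean added sugar content of SSB on the market,
#'   g per litre (default 93).
#' @param baseline_price mean consumer SSB price, GBP per litre
#'   (default 0.61).
#' @param pass_through fraction of a production cost change passed on to
#'   consumer prices; 0.8, 1.0 and 1.2 are the conventional sensitivity
#'   settings, but any value in (0, 10) is accepted.
#' @return object of class `price_assumptions`.
#' @export
price_assumptions <- function(sugar_content = 93,
                              baseline_price = 0.61,
                              pass_through = 1.0) {
  if (sugar_content <= 0) stop("sugar_content must be positive")
  if (baseline_price <= 0) stop("baseline_price must be positive")
  if (pass_through <= 0 || pass_through >= 10) {
    stop("pass_through must be in (0, 10)")
  }
  structure(list(sugar_content = sugar_content,
                 baseline_price = baseline_price,
                 pass_through = pass_through),
            class = "price_assumptions")
}

#' SSB production cost change from levy and sugar price
#'
#' A sugar price change in GBP/tonne raises the cost of a litre of SSB in
#' proportion to its sugar content: `g/l * GBP/t * 1e-6` converts grams
#' per litre and pounds per tonne to pounds per litre. The levy rate is
#' added on top. The unrounded value is carried through all downstream
#' computation; whole-pence figures are for display only.
#'
#' @param sugar_price_change GBP per tonne (e.g. from
#'   [sugar_price_change()]).
#' @param assumptions a [price_assumptions()].
#' @param levy_rate pooled levy in GBP per litre (default 0).
#' @return production cost change in GBP per litre.
#' @export
#' @examples
#' production_cost_change(92, price_assumptions())  # 0.008556 -> "1 p/l"
#' production_cost_change(203, price_assumptions()) # 0.018879 -> "2 p/l"
production_cost_change <- function(sugar_price_change,
                                   assumptions = price_assumptions(),
                                   levy_rate = 0) {
  stopifnot(inherits(assumptions, "price_assumptions"),
            is.numeric(sugar_price_change), is.numeric(levy_rate))
  levy_rate + sugar_price_change * assumptions$sugar_content * 1e-6
}

#' Relative consumer price change under pass-through
#'
#' @param cost_change production cost change, GBP per litre.
#' @param assumptions a [price_assumptions()]; uses `pass_through` and
#'   `baseline_price`.
#' @return relative change in the consumer price (0.38 means +38 %); may
#'   exceed 1 for extreme inputs.
#' @export
#' @examples
#' consumer_price_change(0.23, price_assumptions(pass_through = 1)) # 0.377
consumer_price_change <- function(cost_change,
                                  assumptions = price_assumptions()) {
  stopifnot(inherits(assumptions, "price_assumptions"))
  assumptions$pass_through * cost_change / assumptions$baseline_price
}

# display helper: unrounded GBP/l -> whole pence, half-up
as_pence <- function(gbp_per_litre) {
  floor(gbp_per_litre * 100 + 0.5)
}
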