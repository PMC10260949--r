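#' Describe the sampling distribution of a model parameter
#'
#' Probabilistic sensitivity analysis (PSA) perturbs a fixed set of
#' named model inputs. Each parameter is described by a distribution
#' family, its parameters, optional truncation bounds, and whether one
#' value is drawn per iteration (`per_stratum = FALSE`) or one per
#' stratum. Truncation is exact (inverse-CDF on the truncated support),
#' so draws always respect domain constraints.
#'
#' Recognised parameter names and how their draws enter the model:
#' \describe{
#'   \item{import_share}{replaces the trade scenario's import share of
#'     supply (absolute value).}
#'   \item{exchange_rate}{replaces the trade scenario's GBP/EUR rate
#'     (absolute value; inert for GBP-denominated scenarios).}
#'   \item{ssb_price}{replaces the baseline consumer SSB price, GBP/l.}
#'   \item{price_effect}{replaces the base percent-per-10 % price
#'     effect.}
#'   \item{intake}{multiplies each stratum's baseline intake.}
#'   \item{rr_adjusted, rr_mediated}{multiply the relative risks (one
#'     shared draw across age groups, i.e. fully correlated RR
#'     uncertainty).}
#'   \item{overweight}{multiplies overweight prevalence (clamped to
#'     [0, 1]).}
#'   \item{mortality}{multiplies each stratum's baseline deaths.}
#'   \item{survival}{multiplies all median survivals.}
#' }
#'
#' @param name parameter name (see above).
#' @param family one of "normal", "lognormal", "beta", "gamma", "fixed".
#' @param pars named numeric vector of family parameters: normal
#'   `(mean, sd)`; lognormal `(meanlog, sdlog)`; beta `(shape1,
#'   shape2)`; gamma `(shape, rate)`; fixed `(value)`.
#' @param lower,upper truncation bounds.
#' @param per_stratum draw one value per stratum instead of one per
#'   iteration.
#' @return object of class `psa_distribution`.
#' @export
psa_distribution <- function(name,
                             family = c("normal", "lognormal", "beta",
                                        "gamma", "fixed"),
                             pars,
                             lower = -Inf, upper = Inf,
                             per_stratum = FALSE) {
  family <- match.arg(family)
  need <- switch(family,
                 normal = c("mean", "sd"),
                 lognormal = c("meanlog", "sdlog"),
                 beta = c("shape1", "shape2"),
                 gamma = c("shape", "rate"),
                 fixed = "value")
  if (!all(need %in% names(pars))) {
    stop("family '", family, "' needs parameters: ",
         paste(need, collapse = ", "))
  }
  if (lower >= upper && family != "fixed") {
    stop("lower truncation bound must be below upper")
  }
  structure(list(name = name, family = family, pars = pars,
                 lower = lower, upper = upper,
                 per_stratum = isTRUE(per_stratum)),
            class = "psa_distribution")
}

#' Default PSA distribution set
#'
#' Conventional family choices for each uncertain input: (truncated)
#' normal for prices, the exchange rate and the price effect; beta for
#' the import share; normal multipliers for stratum intake and
#' mortality (truncated at 0); lognormal multipliers for the relative
#' risks; a normal multiplier for overweight prevalence; and a gamma
#' multiplier for survival. All are editable in the scenario config.
#'
#' @return named list of [psa_distribution()] objects.
#' @export
default_psa_distributions <- function() {
  d <- list(
    psa_distribution("import_share", "beta",
                     c(shape1 = 0.64 * 150, shape2 = 0.36 * 150)),
    psa_distribution("exchange_rate", "normal",
                     c(mean = 0.80, sd = 0.04), lower = 0.01),
    psa_distribution("ssb_price", "normal",
                     c(mean = 0.61, sd = 0.03), lower = 0.01),
    psa_distribution("price_effect", "normal",
                     c(mean = 6.7, sd = 0.8), lower = 0.1),
    psa_distribution("intake", "normal",
                     c(mean = 1, sd = 0.15), lower = 0,
                     per_stratum = TRUE),
    psa_distribution("rr_adjusted", "lognormal",
                     c(meanlog = 0, sdlog = 0.05)),
    psa_distribution("rr_mediated", "lognormal",
                     c(meanlog = 0, sdlog = 0.05)),
    psa_distribution("overweight", "normal",
                     c(mean = 1, sd = 0.08), lower = 0,
                     per_stratum = TRUE),
    psa_distribution("mortality", "normal",
                     c(mean = 1, sd = 0.10), lower = 0,
                     per_stratum = TRUE),
    psa_distribution("survival", "gamma",
                     c(shape = 100, rate = 100)))
  stats::setNames(d, vapply(d, `[[`, "", "name"))
}

psa_distributions_from_config <- function(cfg) {
  d <- lapply(cfg, function(x) {
    psa_distribution(x$name, x$family, unlist(x$pars),
                     lower = x$lower %||% -Inf,
                     upper = x$upper %||% Inf,
                     per_stratum = isTRUE(x$per_stratum))
  })
  stats::setNames(d, vapply(d, `[[`, "", "name"))
}

# deterministic per-parameter sub-seed so each parameter has its own
# RNG stream; adding or reordering parameters never perturbs another's
# draws
parameter_seed <- function(master_seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483647
  bitwXor(as.integer(master_seed %% 2147483647L), as.integer(h))
}

# inverse-CDF draws from a (possibly truncated) family
draw_family <- function(dist, n) {
  p <- dist$pars
  if (dist$family == "fixed") return(rep(p[["value"]], n))
  qf <- switch(dist$family,
    normal = function(u) stats::qnorm(u, p[["mean"]], p[["sd"]]),
    lognormal = function(u) stats::qlnorm(u, p[["meanlog"]], p[["sdlog"]]),
    beta = function(u) stats::qbeta(u, p[["shape1"]], p[["shape2"]]),
    gamma = function(u) stats::qgamma(u, p[["shape"]], p[["rate"]]))
  cdf <- switch(dist$family,
    normal = function(x) stats::pnorm(x, p[["mean"]], p[["sd"]]),
    lognormal = function(x) stats::plnorm(x, p[["meanlog"]], p[["sdlog"]]),
    beta = function(x) stats::pbeta(x, p[["shape1"]], p[["shape2"]]),
    gamma = function(x) stats::pgamma(x, p[["shape"]], p[["rate"]]))
  lo <- cdf(dist$lower)
  hi <- cdf(dist$upper)
  qf(stats::runif(n, lo, hi))
}

#' Draw parameter values for PSA iterations
#'
#' Generates, for each parameter, a matrix of draws with one row per
#' iteration (and one column per stratum for per-stratum parameters).
#' Draws are reproducible given `(seed, parameter name)` and
#' independent across parameters: each parameter uses its own RNG
#' stream derived from the master seed and its name, so the draw order
#' of parameters is irrelevant.
#'
#' @param distributions named list of [psa_distribution()] objects.
#' @param n_iterations number of PSA iterations.
#' @param seed master seed.
#' @param n_strata number of strata (for per-stratum parameters).
#' @return named list of numeric matrices, `n_iterations` rows each.
#' @export
draw_parameters <- function(distributions, n_iterations, seed,
                            n_strata = nrow(stratum_grid())) {
  out <- list()
  for (dist in distributions) {
    dim2 <- if (dist$per_stratum) n_strata else 1L
    set.seed(parameter_seed(seed, dist$name))
    out[[dist$name]] <- matrix(draw_family(dist, n_iterations * dim2),
                               nrow = n_iterations, ncol = dim2)
  }
  out
}

# perturb (baseline, scenario) with iteration i of the draws
apply_draws <- function(baseline, scenario, draws, i) {
  g <- function(name) if (name %in% names(draws)) draws[[name]][i, ] else NULL
  v <- g("import_share")
  if (!is.null(v) && !is.null(scenario$trade)) {
    scenario$trade$import_share_of_supply <- min(max(v, 0), 1)
  }
  v <- g("exchange_rate")
  if (!is.null(v) && !is.null(scenario$trade)) {
    scenario$trade$exchange_rate <- v
  }
  v <- g("ssb_price")
  if (!is.null(v)) scenario$price$baseline_price <- v
  v <- g("price_effect")
  if (!is.null(v)) scenario$effect$base_effect <- v
  v <- g("intake")
  if (!is.null(v)) baseline$intake <- baseline$intake * v
  v <- g("rr_adjusted")
  if (!is.null(v)) scenario$rr$rr_adjusted <- scenario$rr$rr_adjusted * v
  v <- g("rr_mediated")
  if (!is.null(v)) scenario$rr$rr_mediated <- scenario$rr$rr_mediated * v
  v <- g("overweight")
  if (!is.null(v)) baseline$overweight <- pmin(pmax(baseline$overweight * v,
                                                    0), 1)
  v <- g("mortality")
  if (!is.null(v)) baseline$deaths <- baseline$deaths * v
  v <- g("survival")
  if (!is.null(v)) {
    for (col in c("surv_diag", "surv_undiag", "surv_none")) {
      baseline[[col]] <- baseline[[col]] * v
    }
  }
  list(baseline = baseline, scenario = scenario)
}

#' Run a probabilistic sensitivity analysis
#'
#' Repeats [run_scenario()] over Monte Carlo draws of the uncertain
#' inputs and summarises total DPP and LYG (and per-quintile DPP) with
#' their empirical 95 % uncertainty intervals, computed as
#' linearly-interpolated 2.5th and 97.5th percentiles over iterations.
#'
#' @param baseline a [baseline_table()].
#' @param scenario a [scenario()].
#' @param distributions named list of [psa_distribution()] objects
#'   (default [default_psa_distributions()]).
#' @param n_iterations number of Monte Carlo iterations (the
#'   conventional production setting is 10 000).
#' @param seed master RNG seed.
#' @return object of class `psa_summary`: list with `draws` (data.frame
#'   of per-iteration outputs, for scatter-style reporting), `summary`
#'   (data.frame: output, mean, lower, upper), `n_iterations`, `seed`.
#' @export
run_psa <- function(baseline, scenario,
                    distributions = default_psa_distributions(),
                    n_iterations = 10000, seed = 1) {
  stopifnot(n_iterations >= 1)
  baseline <- validate_baseline(baseline)
  draws <- draw_parameters(distributions, n_iterations, seed,
                           n_strata = nrow(baseline))
  nq <- length(imd_quintiles())
  dpp <- lyg <- numeric(n_iterations)
  dpp_q <- matrix(NA_real_, n_iterations, nq)
  for (i in seq_len(n_iterations)) {
    pert <- apply_draws(baseline, scenario, draws, i)
    res <- tryCatch(run_scenario(pert$baseline, pert$scenario),
                    error = function(e) {
      stop("PSA iteration ", i, " failed (",
           conditionMessage(e), "); offending draw: ",
           paste(vapply(names(draws), function(nm)
             paste0(nm, "=", signif(draws[[nm]][i, 1], 4)), ""),
             collapse = ", "), call. = FALSE)
    })
    dpp[i] <- res$total[["dpp"]]
    lyg[i] <- res$total[["lyg"]]
    dpp_q[i, ] <- res$by_quintile$dpp
  }
  drawdf <- data.frame(iteration = seq_len(n_iterations),
                       dpp = dpp, lyg = lyg)
  for (qq in seq_len(nq)) drawdf[[paste0("dpp_q", qq)]] <- dpp_q[, qq]
  summ <- do.call(rbind, lapply(names(drawdf)[-1], function(nm) {
    x <- drawdf[[nm]]
    data.frame(output = nm, mean = mean(x),
               lower = unname(stats::quantile(x, 0.025, type = 7)),
               upper = unname(stats::quantile(x, 0.975, type = 7)))
  }))
  rownames(summ) <- NULL
  structure(list(draws = drawdf, summary = summ,
                 n_iterations = n_iterations, seed = seed),
            class = "psa_summary")
}

#' @export
print.psa_summary <- function(x, ...) {
  cat(sprintf("PSA: %d iterations, seed %d\n", x$n_iterations,
              as.integer(x$seed)))
  s <- x$summary[x$summary$output %in% c("dpp", "lyg"), ]
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s: %.0f (95%% UI %.0f, %.0f)\n",
                toupper(s$output[i]), s$mean[i], s$lower[i], s$upper[i]))
  }
  invisible(x)
}
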