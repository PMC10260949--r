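# Shared fixtures: randomized baselines for property tests and a naive
# per-stratum reference implementation of the mortality engine, kept
# deliberately independent of the vectorised production code path.

random_baseline <- function(seed) {
  set.seed(seed)
  g <- stratum_grid()
  n <- nrow(g)
  p_raw <- matrix(runif(3 * n, 0.1, 1), ncol = 3)
  p <- p_raw / rowSums(p_raw)
  validate_baseline(data.frame(
    g,
    deaths = runif(n, 10, 2000),
    population = runif(n, 1e4, 1e6),
    intake = runif(n, 20, 250),
    overweight = runif(n, 0.2, 0.8),
    p_diag = p[, 1], p_undiag = p[, 2], p_none = p[, 3],
    surv_diag = runif(n, 2, 20), surv_undiag = runif(n, 2, 25),
    surv_none = runif(n, 3, 40)))
}

# scalar, loop-based re-derivation of run_scenario totals
naive_total_impact <- function(baseline, scenario) {
  dp_sugar <- if (is.null(scenario$trade)) 0 else {
    ts <- scenario$trade
    acc <- 0
    for (s in names(ts$segment_shares)) {
      acc <- acc + ts$segment_shares[[s]] *
        (ts$tariff_change[[s]] + ts$facilitation_cost[[s]])
    }
    ts$import_share_of_supply * acc *
      (if (ts$currency == "EUR") ts$exchange_rate else 1)
  }
  levy <- if (is.null(scenario$levy)) 0 else {
    l <- scenario$levy
    sum(sapply(names(l$band_rates),
               function(b) l$band_rates[[b]] * l$band_sales_shares[[b]]))
  }
  cost <- levy + dp_sugar * scenario$price$sugar_content / 1e6
  dprice <- scenario$price$pass_through * cost /
    scenario$price$baseline_price

  mult <- ssbimpact:::resolve_multipliers(scenario$effect, baseline)
  dpp <- lyg <- 0
  for (i in seq_len(nrow(baseline))) {
    row <- baseline[i, ]
    grp <- sec_group(row$imd_quintile, scenario$effect$sec_grouping)
    rel <- max(-(scenario$effect$base_effect * mult[[grp]] / 10) * dprice,
               -1)
    dserv <- max(-rel * row$intake / scenario$serving_size, 0)
    rrrow <- scenario$rr[scenario$rr$age_group == row$age_group, ]
    pif <- (1 - rrrow$rr_adjusted^(-dserv)) +
      (1 - rrrow$rr_mediated^(-dserv)) * row$overweight
    pif <- min(max(pif, 0), 1 - 1e-12)
    d <- row$deaths * pif
    dpp <- dpp + d
    lyg <- lyg + d * (row$p_diag * row$surv_diag +
                        row$p_undiag * row$surv_undiag +
                        row$p_none * row$surv_none)
  }
  c(dpp = dpp, lyg = lyg)
}
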