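test_that("potential impact fraction follows the two-pathway closed form", {
  rr <- relative_risk_set(data.frame(age_group = age_groups(),
                                     rr_adjusted = 1.1,
                                     rr_mediated = 1.1))
  # hand arithmetic: 1 - 1.1^-0.5 = 0.04654, mediated share 0.6
  expect_equal(
    mortality_reduction_fraction(0.5, rr, "45-54", 0.6),
    (1 - 1.1^-0.5) * 1.6, tolerance = 1e-9)
  expect_equal(mortality_reduction_fraction(0, rr, "25-34", 0.5), 0)
  null_rr <- relative_risk_set(data.frame(age_group = age_groups(),
                                          rr_adjusted = 1,
                                          rr_mediated = 1))
  expect_equal(mortality_reduction_fraction(0.5, null_rr, "85+", 0.7), 0)
  expect_error(mortality_reduction_fraction(0.5, rr, "15-24", 0.5),
               "age group")
})

test_that("PIF has the log-linear small-effect limit", {
  rr <- default_relative_risks()
  ow <- 0.55
  for (ag in age_groups()) {
    i <- match(ag, age_groups())
    slope <- log(rr$rr_adjusted[i]) + ow * log(rr$rr_mediated[i])
    eps <- 1e-6
    expect_equal(mortality_reduction_fraction(eps, rr, ag, ow) / eps,
                 slope, tolerance = 1e-4)
  }
})

test_that("deaths prevented and life-years gained follow the attribution", {
  expect_equal(deaths_prevented(1000, 0.0745), 74.5)
  expect_equal(deaths_prevented(1000, 0), 0)
  expect_equal(deaths_prevented(1000, 1), 1000)

  pr <- data.frame(p_diag = 0.5, p_undiag = 0.2, p_none = 0.3)
  sv <- data.frame(surv_diag = 8, surv_undiag = 6, surv_none = 15)
  expect_equal(life_years_gained(10, pr, sv), 97)
  expect_equal(life_years_gained(0, pr, sv), 0)
  one <- data.frame(p_diag = 1, p_undiag = 0, p_none = 0)
  expect_equal(life_years_gained(3, one, sv), 3 * 8)
  bad <- data.frame(p_diag = 0.5, p_undiag = 0.2, p_none = 0.2)
  expect_error(life_years_gained(1, bad, sv), "sum to 1")
})

test_that("run_scenario matches a naive per-stratum loop to 1e-9", {
  for (seed in c(3, 17, 42)) {
    b <- random_baseline(seed)
    for (lab in c("levy", "levy+hard")) {
      sc <- standard_scenarios(1)[[lab]]
      got <- run_scenario(b, sc)$total
      want <- naive_total_impact(b, sc)
      expect_equal(got[["dpp"]], want[["dpp"]], tolerance = 1e-9)
      expect_equal(got[["lyg"]], want[["lyg"]], tolerance = 1e-9)
    }
  }
})

test_that("totals are additive over strata and aggregations", {
  b <- random_baseline(9)
  r <- run_scenario(b, standard_scenarios(1)[["levy"]])
  expect_equal(sum(r$strata$dpp), r$total[["dpp"]])
  expect_equal(sum(r$by_age$dpp), r$total[["dpp"]])
  expect_equal(sum(r$by_quintile$lyg), r$total[["lyg"]])
  expect_true(all(r$strata$dpp <= r$strata$deaths))
  expect_true(all(r$strata$lyg >= 0))
})

test_that("null scenario yields zero impact; doubling deaths doubles DPP", {
  b <- random_baseline(12)
  null_sc <- scenario("nothing", levy = NULL, trade = "none")
  r0 <- run_scenario(b, null_sc)
  expect_equal(unname(r0$total), c(0, 0))

  sc <- standard_scenarios(1)[["levy"]]
  b2 <- b
  b2$deaths <- 2 * b$deaths
  expect_equal(run_scenario(b2, sc)$total[["dpp"]],
               2 * run_scenario(b, sc)$total[["dpp"]])
})

test_that("scenario ordering levy <= levy+soft <= levy+hard in DPP and LYG", {
  for (seed in c(4, 21)) {
    b <- random_baseline(seed)
    for (pt in c(0.8, 1.0, 1.2)) {
      res <- lapply(standard_scenarios(pt), function(s) run_scenario(b, s))
      dpps <- vapply(res, function(r) r$total[["dpp"]], numeric(1))
      lygs <- vapply(res, function(r) r$total[["lyg"]], numeric(1))
      expect_true(all(diff(dpps) > 0))
      expect_true(all(diff(lygs) > 0))
    }
  }
})

test_that("Brexit DPP increments track the price increments on any baseline", {
  # the relative DPP gain from adding a Brexit cost increment approaches
  # the relative price increment (small-effect linearity)
  price_ratio_soft <- (0.23 + 92 * 93e-6) / 0.23 - 1
  price_ratio_hard <- (0.23 + 203 * 93e-6) / 0.23 - 1
  for (seed in c(6, 33)) {
    b <- random_baseline(seed)
    res <- lapply(standard_scenarios(1), function(s) run_scenario(b, s))
    soft_inc <- res[["levy+soft"]]$total[["dpp"]] /
      res[["levy"]]$total[["dpp"]] - 1
    hard_inc <- res[["levy+hard"]]$total[["dpp"]] /
      res[["levy"]]$total[["dpp"]] - 1
    expect_equal(soft_inc, price_ratio_soft, tolerance = 0.25)
    expect_equal(hard_inc, price_ratio_hard, tolerance = 0.25)
    expect_lt(soft_inc, price_ratio_soft)  # PIF concavity
    expect_lt(hard_inc, price_ratio_hard)
  }
})
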