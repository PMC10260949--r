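flat_effect <- function() {
  price_effect(sec_multipliers = c(low = 1, mid = 1, high = 1),
               responsiveness_ratio = 1)
}

test_that("relative intake change scales the per-10% effect linearly", {
  eff <- flat_effect()
  expect_equal(relative_intake_change(0.10, eff, 3), -0.067)
  expect_equal(relative_intake_change(0.377, eff, 3), -0.377 * 0.67)
  expect_equal(relative_intake_change(0, eff, 1), 0)
  # cap: intake cannot fall below zero even for huge price rises
  expect_equal(relative_intake_change(10, eff, 5), -1)
  expect_error(relative_intake_change(0.1, eff, 7), "quintile")
})

test_that("SEC gradient holds: deprived reduction is ratio x affluent's", {
  eff <- price_effect()  # multipliers calibrated at application time
  for (p in c(0.05, 0.2, 0.377)) {
    rel <- relative_intake_change(p, eff, 1:5)
    expect_equal(rel[5] / rel[1], 1.65, tolerance = 1e-9)
    expect_equal(rel[1], rel[2])  # pooled quintiles share a group
    expect_equal(rel[4], rel[5])
  }
  # monotonicity: larger price rise, larger (or equal) reduction
  prices <- seq(0, 2, by = 0.1)
  for (q in 1:5) {
    rels <- relative_intake_change(prices, flat_effect(), rep(q,
                                                              length(prices)))
    expect_true(all(diff(rels) <= 1e-12))
  }
})

test_that("calibrated multipliers make the intake-weighted mean effect 1", {
  for (seed in c(2, 11)) {
    b <- random_baseline(seed)
    m <- calibrate_sec_multipliers(b)
    expect_equal(max(m) / min(m), 1.65)
    grp <- sec_group(b$imd_quintile)
    w <- b$population * b$intake
    expect_equal(sum(w * m[grp]) / sum(w), 1, tolerance = 1e-12)
  }
})

test_that("apply_to_baseline yields per-stratum and overall changes", {
  b <- fixture_baseline("uniform")  # identical intake everywhere
  chg <- apply_to_baseline(0.377, flat_effect(), b)
  expect_equal(nrow(chg), 70)
  expect_true(all(abs(chg$relative_change + 0.377 * 0.67) < 1e-12))
  expect_equal(attr(chg, "overall"), -0.377 * 0.67)
  expect_equal(chg$servings_change, chg$absolute_change / 250)

  # zero intake stratum contributes zero absolute change
  b0 <- fixture_baseline("degenerate")
  chg0 <- apply_to_baseline(0.377, flat_effect(), b0)
  expect_true(all(chg0$absolute_change == 0))

  # overall reduction is bracketed by the stratum extremes
  b2 <- random_baseline(5)
  chg2 <- apply_to_baseline(0.3, price_effect(), b2)
  expect_gte(attr(chg2, "overall"), min(chg2$relative_change))
  expect_lte(attr(chg2, "overall"), max(chg2$relative_change))
})

test_that("the default levy price rise gives a ~25% overall intake cut", {
  b <- fixture_baseline("calibrated")
  dprice <- consumer_price_change(0.23, price_assumptions())
  chg <- apply_to_baseline(dprice, price_effect(), b)
  # calibrated multipliers average to 1, so the overall reduction is the
  # base effect scaled to the price change
  expect_equal(attr(chg, "overall"), -0.67 * dprice, tolerance = 1e-9)
})
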