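fixed_dists <- function() {
  list(mortality = psa_distribution("mortality", "fixed",
                                    c(value = 1), per_stratum = TRUE))
}

test_that("parameter draws respect families, truncation and reproducibility", {
  d <- list(
    psa_distribution("overweight", "beta", c(shape1 = 4, shape2 = 2),
                     per_stratum = TRUE),
    psa_distribution("ssb_price", "normal", c(mean = 0.61, sd = 0.5),
                     lower = 0.01),
    psa_distribution("survival", "gamma", c(shape = 100, rate = 100)),
    psa_distribution("price_effect", "fixed", c(value = 6.7)))
  names(d) <- vapply(d, `[[`, "", "name")
  dr <- draw_parameters(d, 500, seed = 11)
  expect_true(all(dr$overweight >= 0 & dr$overweight <= 1))
  expect_equal(dim(dr$overweight), c(500, 70))
  expect_true(all(dr$ssb_price >= 0.01))  # truncation honoured
  expect_true(all(dr$survival > 0))
  expect_true(all(dr$price_effect == 6.7))
  # deterministic under the same seed
  expect_identical(dr, draw_parameters(d, 500, seed = 11))
  # degenerate normal collapses to its mean
  d0 <- list(x = psa_distribution("ssb_price", "normal",
                                  c(mean = 0.61, sd = 0)))
  expect_true(all(draw_parameters(d0, 50, 1)$ssb_price == 0.61))
})

test_that("parameter streams are independent of declaration order", {
  d <- default_psa_distributions()
  dr1 <- draw_parameters(d, 200, seed = 3)
  dr2 <- draw_parameters(rev(d), 200, seed = 3)
  for (nm in names(dr1)) expect_identical(dr1[[nm]], dr2[[nm]])
})

test_that("all-fixed distributions reproduce the deterministic result", {
  b <- fixture_baseline("calibrated")
  sc <- standard_scenarios(1)[["levy"]]
  point <- run_scenario(b, sc)$total
  ps <- run_psa(b, sc, fixed_dists(), n_iterations = 7, seed = 2)
  s <- ps$summary[ps$summary$output == "dpp", ]
  expect_equal(s$mean, point[["dpp"]], tolerance = 1e-12)
  expect_equal(s$lower, point[["dpp"]], tolerance = 1e-12)
  expect_equal(s$upper, point[["dpp"]], tolerance = 1e-12)
})

test_that("PSA summaries are seed-deterministic and well-ordered", {
  b <- fixture_baseline("calibrated")
  sc <- standard_scenarios(1)[["levy"]]
  p1 <- run_psa(b, sc, n_iterations = 300, seed = 9)
  p2 <- run_psa(b, sc, n_iterations = 300, seed = 9)
  expect_identical(p1$summary, p2$summary)
  expect_true(all(p1$summary$lower <= p1$summary$mean))
  expect_true(all(p1$summary$mean <= p1$summary$upper))
  # mean of the PSA is near the point estimate for mild uncertainty
  point <- run_scenario(b, sc)$total[["dpp"]]
  expect_equal(p1$summary$mean[p1$summary$output == "dpp"], point,
               tolerance = 0.1)
})

test_that("fixing a parameter never widens the uncertainty interval", {
  b <- fixture_baseline("calibrated")
  sc <- standard_scenarios(1)[["levy"]]
  d_full <- default_psa_distributions()
  d_less <- d_full
  d_less$price_effect <- psa_distribution("price_effect", "fixed",
                                          c(value = 6.7))
  w <- function(d) {
    s <- run_psa(b, sc, d, n_iterations = 400, seed = 5)$summary
    s$upper[s$output == "dpp"] - s$lower[s$output == "dpp"]
  }
  expect_lt(w(d_less), w(d_full))
})

test_that("UI half-width converges to 1.96 sd for a linear normal input", {
  # with only the per-stratum mortality multipliers stochastic, total
  # DPP is an exact linear combination of independent normals, so the
  # analytic output sd is sigma * sqrt(sum dpp_s^2)
  b <- fixture_baseline("calibrated")
  sc <- standard_scenarios(1)[["levy"]]
  sigma <- 0.1
  d <- list(mortality = psa_distribution(
    "mortality", "normal", c(mean = 1, sd = sigma), per_stratum = TRUE))
  point <- run_scenario(b, sc)
  sd_out <- sigma * sqrt(sum(point$strata$dpp^2))
  ps <- run_psa(b, sc, d, n_iterations = 10000, seed = 4)
  s <- ps$summary[ps$summary$output == "dpp", ]
  half <- (s$upper - s$lower) / 2
  expect_equal(half, 1.96 * sd_out, tolerance = 0.05)
})

test_that("a failing iteration aborts and identifies the draw", {
  b <- fixture_baseline("calibrated")
  sc <- standard_scenarios(1)[["levy"]]
  # an untruncated wide normal on the SSB price eventually drives the
  # baseline price negative, which run_scenario must reject
  d <- list(ssb_price = psa_distribution("ssb_price", "normal",
                                         c(mean = 0.0, sd = 0.1)))
  expect_error(run_psa(b, sc, d, n_iterations = 50, seed = 1),
               "PSA iteration")
})
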