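test_that("default synthetic baseline hits its aggregate calibration targets", {
  b <- synthesize_baseline(synthesis_params(seed = 1))
  expect_equal(nrow(b), 70)
  expect_equal(weighted.mean(b$intake, b$population), 99.5,
               tolerance = 0.5 / 99.5)
  expect_equal(sum(b$deaths), 38000, tolerance = 0.005)
})

test_that("synthetic gradients run the documented directions", {
  b <- synthesize_baseline(synthesis_params(seed = 8))
  ai <- match(b$age_group, age_groups())
  # intake: strictly down with age within sex x quintile
  for (s in sexes()) for (q in 1:5) {
    sel <- b$sex == s & b$imd_quintile == q
    expect_true(all(diff(b$intake[sel][order(ai[sel])]) < 0))
  }
  # higher in men, increasing with deprivation
  expect_true(all(b$intake[b$sex == "male"] >
                    b$intake[b$sex == "female"]))
  for (s in sexes()) for (a in age_groups()) {
    sel <- b$sex == s & b$age_group == a
    ord <- order(b$imd_quintile[sel])
    expect_true(all(diff(b$intake[sel][ord]) > 0))
    expect_true(all(diff(b$deaths[sel][ord]) > 0))
  }
  # deprivation mortality gradient: quintile 5 ~ 2x quintile 1
  q_deaths <- tapply(b$deaths, b$imd_quintile, sum)
  expect_equal(unname(q_deaths[5] / q_deaths[1]), 2, tolerance = 1e-9)
  # overweight within its configured range
  expect_true(all(b$overweight >= 0.3 & b$overweight <= 0.8))
})

test_that("generator is reproducible and degenerate settings flatten it", {
  expect_identical(synthesize_baseline(synthesis_params(seed = 5)),
                   synthesize_baseline(synthesis_params(seed = 5)))
  u <- fixture_baseline("uniform")
  expect_equal(diff(range(u$intake)), 0)
  expect_equal(weighted.mean(u$intake, u$population), 99.5)
  d <- fixture_baseline("degenerate")
  expect_true(all(d$intake == 0))
  expect_error(synthesis_params(sec_slope = -0.5), "infeasible")
})

test_that("mortality disaggregation conserves the projected total", {
  grid <- unique(stratum_grid()[, c("age_group", "sex")])
  # uniform shares: every stratum gets total / 70
  sa <- data.frame(grid, share = 1 / nrow(grid))
  out <- disaggregate_mortality(7000, sa, rep(0.2, 5))
  expect_equal(nrow(out), 70)
  expect_true(all(abs(out$deaths - 100) < 1e-9))

  # arbitrary valid shares still conserve the total
  set.seed(10)
  sh <- runif(nrow(grid)); sh <- sh / sum(sh)
  sec <- runif(5); sec <- sec / sum(sec)
  out2 <- disaggregate_mortality(38000, data.frame(grid, share = sh), sec)
  expect_equal(sum(out2$deaths), 38000)

  # degenerate: all mass in one cell
  one <- data.frame(grid, share = as.numeric(seq_len(nrow(grid)) == 1))
  out3 <- disaggregate_mortality(500, one, c(1, 0, 0, 0, 0))
  expect_equal(max(out3$deaths), 500)
  expect_equal(sum(out3$deaths > 0), 1)

  # integerized split stays exact under largest-remainder correction
  out4 <- disaggregate_mortality(38001, data.frame(grid, share = sh), sec,
                                 integerize = TRUE)
  expect_equal(sum(out4$deaths), 38001)
  expect_true(all(out4$deaths == floor(out4$deaths)))

  expect_error(disaggregate_mortality(100, data.frame(grid, share = sh),
                                      c(0.5, 0.5, 0.5, 0, 0)),
               "sum to 1")
})

test_that("baseline tables round-trip through the delimited text format", {
  b <- synthesize_baseline(synthesis_params(seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_baseline(b, path)
  b2 <- read_baseline(path)
  expect_equal(as.data.frame(b2), as.data.frame(b), tolerance = 1e-12)
  # validation catches broken tables
  bad <- b
  bad$p_none <- bad$p_none + 0.1
  expect_error(validate_baseline(bad), "sum")
  expect_error(validate_baseline(b[-1, ]), "strata")
})
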