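test_that("20-year trailing rates match hand differences", {
  years <- seq(2000, 2050, 10)
  expect_equal(unname(twenty_year_rates(0.5 * (years - 2000), years)),
               rep(5, 4))                      # +0.5 cm/yr everywhere
  expect_equal(unname(twenty_year_rates(rep(2, 6), years)), rep(0, 4))
  r <- twenty_year_rates(c(0, 2, 6, 12), seq(2000, 2030, 10))
  expect_equal(unname(r), c(3, 5))             # hand oracle
  expect_equal(names(r), c("2020", "2030"))
  expect_error(twenty_year_rates(1:4, c(2000, 2010, 2025, 2040)), "decadal")
  expect_error(twenty_year_rates(1:2, c(2000, 2010)), "at least 3")
})

test_that("cumulative_max equals a brute-force prefix maximum", {
  expect_equal(cumulative_max(1:5), 1:5)
  expect_equal(cumulative_max(c(1, 3, 2)), c(1, 3, 3))
  set.seed(3)
  v <- rnorm(100)
  expect_equal(cumulative_max(v), prefix_max(v))
  expect_error(cumulative_max(numeric(0)), "non-empty")
})

test_that("a constant-rate deterministic ensemble reproduces the curve value", {
  g <- seq(-2, 12, length.out = 401)
  cu <- make_curve(g, plogis(-1.5 + 0.5 * g))
  ens <- gen_projection_ensemble(scenario_params(constant_rate_mm = 3,
                                                 n_samples = 5, seed = 1))
  tl <- retreat_timeline(cu, ens)
  expect_equal(tl$probability, rep(curve_lookup(cu, 3), length(tl$years)))
  expect_equal(tl$years, seq(2020, 2300, 10))
})

test_that("a flat curve never crosses a higher threshold", {
  g <- seq(-2, 12, length.out = 101)
  cu <- make_curve(g, rep(0.6, 101))
  ens <- gen_projection_ensemble(scenario_params(constant_rate_mm = 5,
                                                 n_samples = 3, seed = 1))
  tl <- retreat_timeline(cu, ens, threshold = 0.8)
  expect_true(all(tl$probability == 0.6))
  expect_true(is.na(tl$threshold_year))
  expect_equal(threshold_year_table(tl)$year, "not reached")
})

test_that("two constant-rate samples average exactly", {
  g <- seq(-2, 12, length.out = 401)
  cu <- make_curve(g, plogis(-1.5 + 0.5 * g))
  years <- seq(2000, 2100, 10)
  r1 <- 2; r2 <- 8   # mm/yr -> cm per decade = rate
  samples <- rbind(r1 * (years - 2000) / 10, r2 * (years - 2000) / 10)
  ens <- projection_ensemble("S", "RCP8.5", years, samples)
  tl <- retreat_timeline(cu, ens)
  hand <- (curve_lookup(cu, r1) + curve_lookup(cu, r2)) / 2
  expect_equal(tl$probability, rep(hand, length(tl$years)))
})

test_that("timelines are monotone and invariant to sample duplication", {
  g <- seq(-2, 15, length.out = 301)
  cu <- make_curve(g, plogis(-1.5 + 0.5 * g))
  for (seed in 1:3) {
    ens <- gen_projection_ensemble(scenario_params(n_samples = 50, seed = seed))
    tl <- retreat_timeline(cu, ens)
    expect_true(all(diff(tl$probability) >= -1e-12))
    dup <- projection_ensemble(ens$site_id, ens$scenario, ens$years,
                               rbind(ens$samples, ens$samples))
    expect_equal(retreat_timeline(cu, dup)$probability, tl$probability)
  }
})

test_that("pointwise-larger trajectories never cross later", {
  g <- seq(-2, 20, length.out = 301)
  cu <- make_curve(g, plogis(-1.5 + 0.5 * g))
  years <- seq(2000, 2200, 10)
  set.seed(9)
  for (rep in 1:5) {
    base <- apply(matrix(abs(rnorm(10 * length(years), 1, 0.5)),
                         10, length(years)), 1, cumsum)
    base <- t(base)
    higher <- base * 1.8   # pointwise-larger RSL, e.g. a subsiding site
    y_lo <- retreat_timeline(cu, projection_ensemble("A", "x", years, base))
    y_hi <- retreat_timeline(cu, projection_ensemble("A", "x", years, higher))
    expect_true(all(y_hi$probability >= y_lo$probability - 1e-12))
    if (!is.na(y_lo$threshold_year))
      expect_lte(y_hi$threshold_year, y_lo$threshold_year)
  }
})

test_that("threshold years use strict first exceedance on the decadal grid", {
  tl <- structure(list(site_id = "S", scenario = "x",
                       years = c(2030, 2040), probability = c(0.79, 0.83),
                       threshold = 0.8, threshold_year = NA),
                  class = "retreat_timeline")
  g <- seq(0, 10, length.out = 11)
  cu <- make_curve(g, seq(0.5, 0.9, length.out = 11))
  years <- seq(2000, 2100, 10)
  # trajectory whose cumulative-max rate walks up the curve
  samples <- matrix(cumsum(rep(8, length(years))), 1)
  tlr <- retreat_timeline(cu, projection_ensemble("S", "x", years, samples))
  first <- tlr$years[which(tlr$probability > 0.8)[1]]
  expect_equal(tlr$threshold_year, first)
  # table preserves "not reached" and rejects mixed thresholds
  tl2 <- tlr; tl2$threshold <- 0.5
  expect_error(threshold_year_table(list(tlr, tl2)), "mixed thresholds")
})

test_that("ensembles round-trip through the canonical file format", {
  ens <- gen_projection_ensemble(scenario_params(n_samples = 4, seed = 2,
                                                 years = seq(2000, 2100, 10)))
  path <- tempfile(fileext = ".csv")
  write_projection_ensembles(ens, path)
  back <- read_projection_ensembles(path)[[1]]
  expect_equal(back$years, ens$years)
  expect_equal(back$samples, ens$samples, ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(back$scenario, ens$scenario)
})
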