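test_that("the basis is a partition of unity and matches the linear-hat case", {
  x <- runif(50, -4, 9)
  basis <- build_basis(x, K = 12)
  pts <- runif(10000, min(x), max(x))
  B <- eval_basis(basis, pts)
  expect_true(all(B >= 0))
  expect_true(all(abs(rowSums(B) - 1) < 1e-10))
  # degree 1, K = 2 on [0, 1]: plain hat functions
  b2 <- build_basis(c(0, 1), K = 2, degree = 1)
  expect_equal(unname(eval_basis(b2, 0.25)[1, ]), c(0.75, 0.25))
  expect_error(build_basis(x, K = 3, degree = 3), "at least degree")
  expect_error(build_basis(rep(1, 5), K = 6), "distinct")
})

test_that("cubic basis values match an independent Cox-de Boor recursion", {
  basis <- build_basis(c(0, 1), K = 6, degree = 3)
  for (x0 in c(0.05, 0.3, 0.77)) {
    expect_equal(unname(eval_basis(basis, x0)[1, ]),
                 deboor_row(basis$knots, x0, 3), tolerance = 1e-12)
  }
  # and on a non-unit support with more functions
  basis2 <- build_basis(c(-5.5, 10), K = 12, degree = 3)
  xs <- c(-4.2, 0.3, 7.9)
  expect_equal(unname(eval_basis(basis2, xs)),
               deboor_row(basis2$knots, xs, 3), tolerance = 1e-12)
})

test_that("evaluation is clamped (flat) outside the fitted support", {
  basis <- build_basis(c(0, 1), K = 6)
  expect_equal(eval_basis(basis, -3), eval_basis(basis, 0))
  expect_equal(eval_basis(basis, 42), eval_basis(basis, 1))
})

test_that("every retained draw satisfies the monotonicity constraint", {
  sim <- make_sim_dataset(300, seed = 21)
  post <- fit_tendency_model(sim, quick_config(seed = 21))
  alpha <- post$draws[, seq_len(post$basis$K)]
  expect_true(all(t(apply(alpha, 1, diff)) >= 0))
  # consequence: each draw's curve is non-decreasing on a fine grid
  grid <- seq(post$basis$support[1], post$basis$support[2], length.out = 1000)
  A <- eval_basis(post$basis, grid)
  for (i in sample(nrow(alpha), 25))
    expect_true(all(diff(A %*% alpha[i, ]) >= -1e-10))
  cu <- probability_curve(post, grid)
  expect_true(all(diff(cu$mean) >= -1e-12))
  expect_true(all(cu$lo <= cu$mean & cu$mean <= cu$hi))
  expect_true(all(cu$lo > 0 & cu$hi < 1))
})

test_that("single-class data yield a flagged, boundary-degenerate posterior", {
  sim <- list(x = runif(200, -2, 8), y = rep(1L, 200))
  w <- capture_warnings(post <- fit_tendency_model(sim, quick_config(seed = 3)))
  expect_match(w, "single response class", all = FALSE)
  expect_true(post$degenerate)
  cu <- probability_curve(post)
  expect_true(all(cu$mean > 0.9))
})

test_that("input validation rejects malformed datasets", {
  expect_error(fit_tendency_model(list(x = c(1, NaN), y = c(0, 1)),
                                  quick_config()), "non-finite")
  expect_error(fit_tendency_model(list(x = c(1, 2), y = c(0, 2)),
                                  quick_config()), "binary")
  expect_error(model_config(iter = 100, burn = 200), "exceed")
  expect_error(model_config(chains = 1), "2 chains")
})

test_that("the same seed and config reproduce the draw sequence exactly", {
  sim <- make_sim_dataset(150, seed = 5)
  p1 <- fit_tendency_model(sim, quick_config(seed = 99))
  p2 <- fit_tendency_model(sim, quick_config(seed = 99))
  expect_identical(p1$draws, p2$draws)
  p3 <- fit_tendency_model(sim, quick_config(seed = 100))
  expect_false(identical(p3$draws, p1$draws))
})

test_that("the prior alone does not pin the probability curve", {
  # zero-length data: the likelihood contributes nothing, so draws come from
  # the prior; implied curves should range over (0, 1) rather than cluster
  basis <- build_basis(c(0, 10), K = 8)
  Cd <- matrix(numeric(0), nrow = 0, ncol = 7)
  set.seed(4)
  res <- marshretreat:::mcmc_pspline_chain(
    Cd, integer(0), 4000L, 2000L, 2L, TRUE, 10, 1,
    c(0, rep(0.01, 7), 0))
  alpha1 <- res$draws[, 1]
  p_left <- plogis(alpha1)
  expect_lt(quantile(p_left, 0.1), 0.1)
  expect_gt(quantile(p_left, 0.9), 0.9)
})

test_that("posterior summaries behave on degenerate and analytic curves", {
  sim <- make_sim_dataset(100, seed = 8)
  post <- fit_tendency_model(sim, quick_config(seed = 8))
  post1 <- post
  post1$draws <- post$draws[1, , drop = FALSE]
  post1$chain <- post$chain[1]
  cu1 <- probability_curve(post1, seq(-4, 8, length.out = 50))
  expect_equal(cu1$lo, cu1$mean)
  expect_equal(cu1$hi, cu1$mean)
  post0 <- post; post0$draws <- post$draws[0, , drop = FALSE]
  expect_error(probability_curve(post0), "no draws")
})

test_that("rate_at_probability inverts a symmetric curve and reports misses", {
  centre <- 2.5
  g <- seq(-5, 10, length.out = 301)
  cu <- make_curve(g, plogis(0.8 * (g - centre)))
  expect_equal(rate_at_probability(cu, 0.5), centre, tolerance = 0.05,
               ignore_attr = TRUE)
  miss <- rate_at_probability(cu, 0.9999)
  expect_true(is.na(miss))
  expect_match(attr(miss, "status"), "above curve maximum")
  low <- rate_at_probability(make_curve(g, rep(0.5, 301) + g * 1e-6), 0.4)
  expect_equal(unclass(low)[1], g[1], ignore_attr = TRUE)
})

test_that("posterior artifacts round-trip through JSON", {
  sim <- make_sim_dataset(120, seed = 13)
  post <- fit_tendency_model(sim, quick_config(seed = 13))
  path <- tempfile(fileext = ".json")
  write_posterior(post, path)
  back <- read_posterior(path)
  expect_equal(back$draws, post$draws)
  expect_equal(back$basis$knots, post$basis$knots)
  expect_equal(back$config$seed, post$config$seed)
  expect_equal(curve_lookup(probability_curve(back), c(-2, 3)),
               curve_lookup(probability_curve(post), c(-2, 3)))
})
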