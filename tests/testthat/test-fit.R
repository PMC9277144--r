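test_that("goodness of fit matches its definitions", {
  y <- c(1, 2, 3)
  perfect <- goodness_of_fit(y, y, 1)
  expect_equal(perfect$sse, 0); expect_equal(perfect$r2, 1)
  at_mean <- goodness_of_fit(y, rep(mean(y), 3), 1)
  expect_equal(at_mean$r2, 0)
  g <- goodness_of_fit(y, c(1, 2, 4), 1)
  expect_equal(g$sse, 1); expect_equal(g$dof, 2)
  expect_equal(g$se, sqrt(1 / 2), tolerance = 1e-6)   # ~0.707
  expect_equal(g$t_crit, qt(0.975, 2))
  expect_error(goodness_of_fit(c(2, 2, 2), c(1, 2, 3), 1),
               class = "sulfkin_degenerate_fit")
})

test_that("a single point with fixed order is interpolated exactly", {
  c0 <- 1000; fv <- 1 / 24; k_true <- 0.05
  ca <- pfr_outlet_concentration(c0, k_true, 1, 1 / fv)
  pts <- tibble::tibble(flow_per_volume = fv, c0 = c0, ca = ca,
                        y = fv * (c0 - ca))
  fit <- fit_kinetics(pts, order_fixed = 1)
  expect_equal(fit$k, k_true, tolerance = 1e-10)
  expect_equal(fit$sse, 0)
  expect_equal(fit$dof, 0L)
})

test_that("noiseless ladders recover both kinetic truths", {
  # first-order truth
  obs_l <- simulate_observations(noiseless_lactate(), seed = 1)
  pts_l <- build_rate_points(obs_l, noiseless_lactate()$config)
  fit_l <- fit_kinetics(pts_l, order_fixed = 1)
  expect_equal(fit_l$k, 0.06955, tolerance = 1e-3)     # 0.1% relative
  free_l <- fit_kinetics(pts_l)
  expect_equal(free_l$n, 1, tolerance = 0.05)
  # high-order truth
  obs_a <- simulate_observations(noiseless_acetate(), seed = 1)
  pts_a <- build_rate_points(obs_a, noiseless_acetate()$config)
  free_a <- fit_kinetics(pts_a)
  expect_lt(abs(free_a$n - 2.9), 0.05)
  expect_equal(free_a$k, 1.5e-7, tolerance = 0.05)
})

test_that("fit SSE never exceeds the 40x40 grid-search oracle", {
  spec <- scenario_lactate_reactor(noise_cv = 0.05, replicates = 5)
  for (seed in c(3, 17)) {
    obs <- simulate_observations(spec, seed = seed)
    pts <- build_rate_points(obs, spec$config)
    fit <- fit_kinetics(pts)
    expect_lte(fit$sse, grid_search_sse(pts) * (1 + 1e-12))
  }
})

test_that("repeated fits agree and ties break toward smaller order", {
  spec <- scenario_acetate_reactor(noise_cv = 0.05, replicates = 5)
  obs <- simulate_observations(spec, seed = 5)
  pts <- build_rate_points(obs, spec$config)
  f1 <- fit_kinetics(pts); f2 <- fit_kinetics(pts)
  expect_equal(f1$sse, f2$sse, tolerance = 1e-8)
  expect_equal(f1$n, f2$n, tolerance = 1e-6)
  expect_gte(nrow(f1$trace), 8)   # multi-start trace retained
})

test_that("degenerate and underdetermined inputs raise typed errors", {
  pts0 <- tibble::tibble(flow_per_volume = c(0.1, 0.2), c0 = 1000,
                         ca = 1000, y = c(0, 0))
  expect_error(fit_kinetics(pts0, order_fixed = 1),
               class = "sulfkin_degenerate_fit")
  pts1 <- tibble::tibble(flow_per_volume = c(0.1, 0.2), c0 = 1000,
                         ca = c(900, 950), y = c(10, 10))
  expect_error(fit_kinetics(pts1), class = "sulfkin_data_error")  # free n, 2 pts
})

test_that("confidence bands have the t-based constant half-width", {
  spec <- scenario_lactate_reactor(noise_cv = 0.05, replicates = 5)
  obs <- simulate_observations(spec, seed = 9)
  pts <- build_rate_points(obs, spec$config)
  fit <- fit_kinetics(pts, order_fixed = 1)
  fv <- seq(0.01, 0.12, length.out = 7)
  band <- confidence_band(fit, c0 = 1000, fv_grid = fv)
  expect_equal(band$upr - band$fit, rep(fit$t_crit * fit$se, 7))
  expect_equal(band$fit - band$lwr, rep(fit$t_crit * fit$se, 7))
  # dof = 5 two-tailed 95% quantile
  expect_equal(qt(0.975, 5), 2.5706, tolerance = 1e-4)
  # normal limit for large dof
  expect_equal(qt(0.975, 1e6), 1.96, tolerance = 1e-3)
  # a perfect fit collapses the band onto the curve
  obs0 <- simulate_observations(noiseless_lactate(), seed = 1)
  fit0 <- fit_kinetics(build_rate_points(obs0, noiseless_lactate()$config),
                       order_fixed = 1)
  band0 <- confidence_band(fit0, 1000, fv)
  expect_equal(band0$lwr, band0$fit, tolerance = 1e-4)
})

test_that("tidy and glance expose the fit in broom form", {
  obs <- simulate_observations(noiseless_lactate(), seed = 1)
  fit <- fit_kinetics(build_rate_points(obs, noiseless_lactate()$config),
                      order_fixed = 1)
  td <- tidy(fit)
  expect_equal(td$term, c("k", "n"))
  expect_true(td$fixed[td$term == "n"])
  gl <- glance(fit)
  expect_equal(gl$k, fit$k)
  expect_equal(gl$dof, fit$dof)
})
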