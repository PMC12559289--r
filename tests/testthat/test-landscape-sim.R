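# Virtual-landscape generator: covariate formulas, latent-field moments and
# the assembled probability surface.

test_that("bathymetry follows 100*log(xy+1) and stays within 0-800 m", {
  g <- structure(list(x = c(0, 1), y = c(0, exp(1) - 1), years = 1:2),
                 class = "grid_domain")
  b <- make_bathymetry(g)
  expect_equal(b[1, 1], 0)                       # log(1) = 0
  expect_equal(b[2, 2], 100)                     # 100 * log(e)
  expect_lte(max(make_bathymetry(grid_domain())), 800 + 1e-6)
  expect_equal(max(make_bathymetry(grid_domain())), 800)  # corner attains 800

  too_big <- structure(list(x = c(1, 100), y = c(1, 100), years = 1:2),
                       class = "grid_domain")
  expect_error(make_bathymetry(too_big), "configuration error")
})

test_that("temperature is sqrt(y+1)+10 plus exactly 0.5 per year", {
  g <- structure(list(x = c(1, 2), y = c(0, 3), years = 1:4),
                 class = "grid_domain")
  t1 <- make_temperature(g, year = 1)
  expect_equal(t1[1, 1], 11.0)                   # sqrt(1) + 10
  expect_equal(t1[1, 2], 12.0)                   # sqrt(4) + 10
  expect_equal(make_temperature(g, year = 3)[1, 1], 12.0)  # 11 + 2 * 0.5
  arr <- make_temperature(g)
  for (t in 2:4)
    expect_equal(arr[, , t] - arr[, , t - 1],
                 matrix(0.5, 2, 2))
  expect_error(make_temperature(g, year = 9), "not in grid")
  gneg <- structure(list(x = 1:2, y = c(-2, 1), years = 1:2),
                    class = "grid_domain")
  expect_error(make_temperature(gneg), "negative")
})

test_that("temporal trend matches AR(1) theory", {
  n_series <- 1000
  # white-noise limit: pooled lag-1 product moment near zero (the centred
  # per-series estimator carries a -1/(n-1) small-sample bias)
  sims0 <- vapply(seq_len(n_series), function(i)
    simulate_temporal_trend(1:20, rho_t = 0, seed = 5000 + i), numeric(20))
  expect_lt(abs(mean(sims0[-1, ] * sims0[-20, ])), 0.03)
  # rho_t = 0.7: pooled lag-1 autocorrelation approx 0.7, unit variance
  sims <- vapply(seq_len(n_series), function(i)
    simulate_temporal_trend(1:20, rho_t = 0.7, seed = i), numeric(20))
  lag1 <- mean(sims[-1, ] * sims[-20, ])
  expect_equal(lag1, 0.7, tolerance = 0.05 / 0.7)
  expect_equal(mean(sims^2), 1, tolerance = 0.1)
  expect_identical(simulate_temporal_trend(1:20, 0.7, seed = 3),
                   simulate_temporal_trend(1:20, 0.7, seed = 3))
})

test_that("spatio-temporal field matches its AR(1)/Matern oracles", {
  g <- grid_domain(nx = 6, ny = 6, xmax = 10, ymax = 10, years = 1:4)
  n_rep <- 200
  sims <- lapply(seq_len(n_rep), function(i)
    simulate_spatiotemporal_field(g, range = 3, sigma = 1, rho = 0.7,
                                  seed = 100 + i))
  # stationary marginal variance sigma^2 = 1 (MC tolerance 10%)
  expect_equal(mean(vapply(sims, function(u) mean(u^2), numeric(1))),
               1, tolerance = 0.1)
  # rho = 0: years are independent innovations
  sims0 <- lapply(seq_len(n_rep), function(i)
    simulate_spatiotemporal_field(g, range = 3, sigma = 1, rho = 0,
                                  seed = 300 + i))
  lag1 <- mean(vapply(sims0, function(u)
    mean(u[, , -1] * u[, , -4]), numeric(1)))
  expect_lt(abs(lag1), 0.05)

  # spatial correlation decays: distance `range` well above distance 3*range,
  # in line with the Matern oracle evaluated at those distances
  r <- 3
  near <- mean(vapply(sims, function(u)
    mean(u[1:3, , 1] * u[4:6, , 1]), numeric(1)))     # ~ lag-3 in x
  far <- mean(vapply(sims, function(u)
    mean(u[1, , 1] * u[6, , 1]), numeric(1)))
  oracle_near <- matern_correlation(10 / 6 * 3, r)    # 3-cell offset = 5 units
  oracle_far <- matern_correlation(10 / 6 * 5, r)
  expect_gt(oracle_near, oracle_far)
  expect_gt(near, far)
  expect_gt(near, 2 * far)

  # seeded reproducibility; different seeds decorrelate
  expect_identical(sims[[1]],
                   simulate_spatiotemporal_field(g, 3, 1, 0.7, seed = 101))
  expect_false(identical(sims[[1]], sims[[2]]))
})

test_that("assembled probabilities obey the link and coefficient signs", {
  g <- small_grid()
  # all coefficients and fields zero -> pi = 0.5 everywhere
  cfg0 <- scenario_config("persistent", beta0 = 0, bath_coeffs = 0,
                          temp_coeff = 0)
  s0 <- assemble_probability(cfg0, g)
  expect_true(all(s0$pi == 0.5))

  # persistent defaults: monotone increasing in bathymetry at fixed year,
  # monotone decreasing in temperature
  cfg <- scenario_config("persistent")
  expect_equal(cfg$bath_coeffs, 7.5)
  expect_equal(cfg$temp_coeff, -0.8)
  expect_equal(cfg$spatial_range, 5.6)
  expect_equal(cfg$rho_st, 0.1)
  s <- assemble_probability(scenario_config("persistent", temp_coeff = 0), g)
  bath <- s$covariates$bathymetry
  ord <- order(as.vector(bath))
  expect_true(all(diff(as.vector(s$pi[, , 1])[ord]) >= 0))
  s_t <- assemble_probability(scenario_config("persistent", bath_coeffs = 0), g)
  temp1 <- s_t$covariates$temperature[, , 1]
  ordt <- order(as.vector(temp1))
  expect_true(all(diff(as.vector(s_t$pi[, , 1])[ordt]) <= 0))

  # cosmopolitan defaults stored as documented
  cc <- scenario_config("cosmopolitan")
  expect_equal(cc$spatial_range, 3.5)
  expect_equal(cc$rho_st, 0.7)
  expect_equal(cc$bath_coeffs, c(-1.5, -1.1))
  expect_equal(cc$rho_t, 0.7)

  # pi is always a probability; U and trend shift the logit additively
  w <- small_world("cosmopolitan")
  expect_true(all(w$surface$pi >= 0 & w$surface$pi <= 1))
  expect_equal(w$surface$pi, plogis(w$surface$eta))
})

test_that("sigma -> 0 with a flat trend gives a deterministic response surface", {
  g <- small_grid()
  cfg <- scenario_config("persistent", spatial_sd = 0, seed = 1)
  s1 <- assemble_probability(cfg, g,
                             U = simulate_spatiotemporal_field(g, 5.6, 0, 0.1, 1),
                             trend = numeric(length(g$years)))
  s2 <- assemble_probability(cfg, g,
                             U = simulate_spatiotemporal_field(g, 5.6, 0, 0.1, 99),
                             trend = numeric(length(g$years)))
  expect_identical(s1$pi, s2$pi)  # independent of the (degenerate) field seed
})

test_that("occurrence draws are Bernoulli(pi)", {
  g <- small_grid()
  cfg <- scenario_config("persistent", bath_coeffs = 0, temp_coeff = 0)
  s <- assemble_probability(cfg, g)

  s1 <- s; s1$pi[] <- 1
  expect_true(all(draw_occurrence(s1, 1)$occurrence == 1))
  s0 <- s; s0$pi[] <- 0
  expect_true(all(draw_occurrence(s0, 1)$occurrence == 0))

  big <- grid_domain(nx = 100, ny = 100, years = 1:1)
  sb <- assemble_probability(scenario_config("persistent", bath_coeffs = 0,
                                             temp_coeff = 0), big)
  sb$pi[] <- 0.3
  frac <- mean(draw_occurrence(sb, 11)$occurrence)
  expect_equal(frac, 0.3, tolerance = 0.02 / 0.3)  # binomial SE ~ 0.005

  expect_identical(draw_occurrence(s, 5)$occurrence,
                   draw_occurrence(s, 5)$occurrence)
})

test_that("simulated worlds are reproducible and exportable", {
  w1 <- small_world(seed = 11)
  w2 <- small_world(seed = 11)
  expect_identical(w1$field$occurrence, w2$field$occurrence)
  expect_false(identical(w1$field$occurrence,
                         small_world(seed = 12)$field$occurrence))
  df <- simulation_table(w1)
  expect_equal(nrow(df), 10 * 10 * 6)
  expect_true(all(df$occurrence %in% 0:1))
  # bathymetry static over time: same values every year
  expect_equal(unique(vapply(split(df$bathymetry, df$year), sum, numeric(1))),
               sum(df$bathymetry[df$year == 1]))
})
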