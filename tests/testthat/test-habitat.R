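# Habitat-projection pipeline on purely synthetic fixtures.

habitat_fixture <- function(seed = 21) {
  w <- small_world("persistent", seed = seed)
  stack <- world_to_stack(w)
  tab <- sample_true(w, n = 60, seed = seed)
  list(world = w, stack = stack, tab = as.data.frame(tab))
}

fast_variant <- function(tab, stack, variant = "suitable_habitat", seed = 1) {
  fit_variant(tab, stack, variant,
              config = bart_config(n_trees = 30, n_draws = 100, n_burn = 30,
                                   seed = seed))
}

test_that("stack standardization is a reference-period z-score and inverts", {
  fx <- habitat_fixture()
  std <- standardize_stack(fx$stack, reference_years = 1:4)
  for (nm in names(std$layers)) {
    ref <- std$layers[[nm]][, , 1:4]
    expect_equal(mean(ref), 0, tolerance = 1e-10)
    expect_equal(sd(as.vector(ref)), 1, tolerance = 1e-10)
  }
  # future warming by delta maps to delta / sigma on the standardized scale
  warmed <- fx$stack
  warmed$layers$sst[, , 5:6] <- warmed$layers$sst[, , 5:6] + 3
  stdw <- standardize_stack(warmed, reference_years = 1:4)
  sig <- stdw$standardization$params$sst["sigma"]
  base_future <- standardize_stack(fx$stack, 1:4)$layers$sst[, , 5:6]
  expect_equal(stdw$layers$sst[, , 5:6] - base_future,
               array(3 / sig, dim = c(10, 10, 2)), tolerance = 1e-10)

  # standardizing an already standardized stack is the identity
  expect_equal(standardize_stack(std, reference_years = 1:4)$layers,
               std$layers, tolerance = 1e-10)
  # and inverting recovers the raw layers to machine precision
  expect_equal(unstandardize_stack(std)$layers, fx$stack$layers,
               tolerance = 1e-12)

  flat <- fx$stack
  flat$layers$sst[] <- 7
  expect_error(standardize_stack(flat), "`sst` has zero variance")
})

test_that("model variants use the covariates they claim", {
  fx <- habitat_fixture()
  m_env <- fast_variant(fx$tab, fx$stack, "suitable_habitat")
  expect_setequal(m_env$fit$varnames, c("bathymetry", "sst"))
  m_nat <- fast_variant(fx$tab, fx$stack, "native_range")
  expect_setequal(m_nat$fit$varnames, c("bathymetry", "sst", "x", "y"))

  expect_error(fit_variant(fx$tab[, c("year", "label")], fx$stack,
                           "native_range"), "coordinate columns")

  # same data, same seed: identical surfaces (and the environment-only model
  # never sees the coordinate columns at all)
  m_env2 <- fast_variant(fx$tab, fx$stack, "suitable_habitat")
  p1 <- project_years(m_env, fx$stack, years = 1:2, n_draws = 50)
  p2 <- project_years(m_env2, fx$stack, years = 1:2, n_draws = 50)
  expect_identical(p1$mean, p2$mean)
})

test_that("native ranges are narrower than suitable habitat on clustered data", {
  # presences clustered in one corner; environment nearly uninformative, so
  # only the coordinates can localize the species
  w <- small_world("persistent", seed = 31)
  stack <- world_to_stack(w)
  set.seed(31)
  corner <- expand.grid(ix = 1:3, iy = 1:3)
  out <- expand.grid(ix = 1:10, iy = 1:10)
  pres <- corner[sample(nrow(corner), 25, replace = TRUE), ]
  abs_ <- out[sample(nrow(out), 25, replace = TRUE), ]
  tab <- data.frame(
    x = stack$x[c(pres$ix, abs_$ix)], y = stack$y[c(pres$iy, abs_$iy)],
    year = rep(1:4, length.out = 50),
    label = rep(c(1L, 0L), each = 25))
  flatstack <- stack
  flatstack$layers$bathymetry[] <- jitter(flatstack$layers$bathymetry[] * 0 + 1,
                                          amount = 1e-3)
  flatstack$layers$sst[] <- jitter(flatstack$layers$sst[] * 0 + 1,
                                   amount = 1e-3)
  m_nat <- fast_variant(tab, flatstack, "native_range", seed = 4)
  m_env <- fast_variant(tab, flatstack, "suitable_habitat", seed = 4)
  a_nat <- mean(period_mean(project_years(m_nat, flatstack, 1:4, 50)) > 0.5)
  a_env <- mean(period_mean(project_years(m_env, flatstack, 1:4, 50)) > 0.5)
  expect_lt(a_nat, a_env)
})

test_that("projections carry valid envelopes and respond to forcing trends", {
  fx <- habitat_fixture()
  std <- standardize_stack(fx$stack, reference_years = 1:4)
  model <- fast_variant(fx$tab, std)
  proj <- project_years(model, std, n_draws = 80)
  expect_equal(dim(proj$mean), c(10, 10, 6))
  expect_true(all(proj$lower <= proj$mean + 1e-12 &
                  proj$mean <= proj$upper + 1e-12))
  expect_error(project_years(model, std, years = c(1, 99)), "missing layer-years")

  # stationary covariates: identical yearly inputs give identical surfaces
  statstack <- std
  for (t in 2:6) statstack$layers$sst[, , t] <- statstack$layers$sst[, , 1]
  projs <- project_years(model, statstack, n_draws = 80)
  for (t in 2:6) expect_equal(projs$mean[, , t], projs$mean[, , 1])

  # monotone warming with a negative fitted temperature response pushes the
  # yearly mean probability down
  set.seed(8)
  n <- 150
  sst_v <- runif(n, -2, 2)
  lab <- rbinom(n, 1, plogis(-3 * sst_v))
  warm <- std
  for (t in 1:6) warm$layers$sst[, , t] <- matrix(sst_v[1:100], 10, 10) +
      0.6 * (t - 1)
  mdl <- structure(
    list(fit = bart_probit(cbind(bathymetry = rep(1, n), sst = sst_v), lab,
                           bart_config(n_trees = 30, n_draws = 100,
                                       n_burn = 30, seed = 2)),
         variant = "suitable_habitat",
         layer_names = names(warm$layers)),
    class = "habitat_model")
  pw <- project_years(mdl, warm, n_draws = 80)
  yearly <- apply(pw$mean, 3, mean)
  expect_lt(yearly[6], yearly[1])
  expect_lt(cor(1:6, yearly) , 0)
})

test_that("change maps and percent change agree algebraically", {
  fx <- habitat_fixture()
  model <- fast_variant(fx$tab, fx$stack)
  proj <- project_years(model, fx$stack, n_draws = 60)
  hist <- proj; hist$years <- 1:3; hist$mean <- proj$mean[, , 1:3]
  hist$lower <- proj$lower[, , 1:3]; hist$upper <- proj$upper[, , 1:3]
  fut <- proj; fut$years <- 4:6; fut$mean <- proj$mean[, , 4:6]
  fut$lower <- proj$lower[, , 4:6]; fut$upper <- proj$upper[, , 4:6]

  expect_equal(change_map(hist, hist), matrix(0, 10, 10))
  shifted <- hist
  shifted$mean <- hist$mean + 0.1
  expect_equal(change_map(hist, shifted), matrix(0.1, 10, 10),
               tolerance = 1e-12)
  expect_equal(change_map(hist, fut), -change_map(fut, hist))

  pc <- percent_change(hist, fut, future_years = fut$years)
  cm <- change_map(hist, fut)
  expect_equal(pc, 100 * mean(cm) / mean(period_mean(hist)))

  # direct formula: hist mean 0.5, future mean 0.6 -> +20%
  h2 <- hist; h2$mean[] <- 0.5
  f2 <- fut; f2$mean[] <- 0.6
  expect_equal(percent_change(h2, f2, future_years = f2$years), 20)
  expect_equal(percent_change(h2, h2, future_years = h2$years), 0)
  f0 <- fut; f0$mean[] <- 0
  expect_equal(percent_change(h2, f0, future_years = f0$years), -100)
  hz <- hist; hz$mean[] <- 0
  expect_error(percent_change(hz, f2), "zero")

  # default future window drops the terminal year, then keeps 10
  long <- proj; long$years <- 1:15
  expect_equal(future_window(long), 5:14)
})

test_that("richness stacking and group aggregation count and order correctly", {
  fx <- habitat_fixture()
  model <- fast_variant(fx$tab, fx$stack)
  proj <- project_years(model, fx$stack, n_draws = 50)
  ones <- proj; ones$mean[] <- 1
  zeros <- proj; zeros$mean[] <- 0
  seven <- replicate(7, ones, simplify = FALSE)
  expect_equal(richness_stack(seven, rep(0.5, 7)), matrix(7L, 10, 10))
  expect_equal(richness_stack(list(zeros, zeros), c(0.5, 0.5)),
               matrix(0L, 10, 10))
  mix <- list(ones, zeros, proj)
  r <- richness_stack(mix, rep(0.5, 3))
  expect_true(all(r >= 1 & r <= 3))

  # single species: aggregation is the identity
  expect_equal(functional_group_aggregate(list(proj))$mean, proj$mean)
  # median of {0.2, 0.5, 0.8}
  a <- proj; a$mean[] <- 0.2
  b <- proj; b$mean[] <- 0.5
  c_ <- proj; c_$mean[] <- 0.8
  agg <- functional_group_aggregate(list(a, b, c_))
  expect_true(all(agg$mean == 0.5))
  # invariant to species ordering
  agg2 <- functional_group_aggregate(list(c_, a, b))
  expect_equal(agg$mean, agg2$mean)
})

test_that("forward validation scores held-out years at the Youden cutoff", {
  fx <- habitat_fixture()
  model <- fast_variant(fx$tab, fx$stack)
  proj <- project_years(model, fx$stack, n_draws = 60)
  w <- fx$world
  hold <- as.data.frame(sample_true(w, n = 50, seed = 77, years = 5:6))
  cm <- forward_validation(proj, hold)
  expect_s3_class(cm, "confusion_summary")
  expect_true(cm$SEN >= 0 && cm$SEN <= 1)

  # records in cells projected at p = 1 are always detected
  sure <- proj; sure$mean[] <- 1
  pres_only <- hold[hold$label == 1, ]
  pv <- forward_validation(sure, pres_only, cutoff = 0.5)
  expect_equal(pv$SEN, 1)
  expect_error(forward_validation(sure, pres_only), "explicit cutoff")

  none <- hold; none$year <- none$year + 100
  expect_error(forward_validation(proj, none), "no overlapping years")
  empty <- hold[hold$label == 0, ]
  expect_error(forward_validation(proj, empty), "no presence records")
})

test_that("stacks and occurrence cleaning round-trip as plain text", {
  fx <- habitat_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_stack_csv(fx$stack, path)
  back <- read_stack_csv(path)
  expect_equal(back$layers$bathymetry, fx$stack$layers$bathymetry,
               tolerance = 1e-10)
  expect_equal(back$layers$sst, fx$stack$layers$sst, tolerance = 1e-10)
  expect_equal(back$years, fx$stack$years)

  dup <- rbind(fx$tab, fx$tab[1:5, ])
  cleaned <- clean_occurrences(dup)
  expect_equal(nrow(cleaned), nrow(fx$tab))
})
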