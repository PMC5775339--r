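test_that("the default configuration yields the expected sample volume", {
  x <- generate_samples(seed = 1)
  expect_true(abs(x$n_samples - 879) / 879 < 0.05)
  expect_equal(x$years, 1997:2016)
  expect_false(any(x$samples$presence_only))
  expect_true(all(x$items$wet_mass_g > 0))
})

test_that("a fixed seed reproduces the table exactly", {
  a <- generate_samples(seed = 77)
  b <- generate_samples(seed = 77)
  expect_identical(a$samples, b$samples)
  expect_identical(a$items, b$items)
  c2 <- generate_samples(seed = 78)
  expect_false(identical(a$items, c2$items))
})

test_that("regime-conditional occurrence rates match the configuration", {
  fo1 <- fo2 <- numeric(0)
  for (seed in 1:25) {
    x <- generate_samples(seed = seed)
    fo1 <- c(fo1, frequency_of_occurrence(x, "polar_cod",
                                          years = 1997:2006))
    fo2 <- c(fo2, frequency_of_occurrence(x, "polar_cod",
                                          years = 2007:2016))
  }
  expect_lt(abs(mean(fo1) - 80), 5)
  expect_lt(abs(mean(fo2) - 30), 5)
})

test_that("meal masses are right-skewed with the configured mean", {
  x <- generate_samples(seed = 10)
  mm <- average_meal_mass(x, "polar_cod")
  # lognormal mean 17.2 g, ~500 occurrences: generous 3-SE band
  expect_lt(abs(mm$mean - 17.2), 3 * 17.2 * sqrt(exp(0.64) - 1) /
              sqrt(mm$n_occ))
  masses <- x$items$wet_mass_g[x$items$taxon == "polar_cod"]
  expect_gt(mean(masses), stats::median(masses))  # right skew
})

test_that("herring never occurs before its first configured year", {
  x <- generate_samples(seed = 6)
  yr <- x$samples$year[match(x$items$sample_id, x$samples$sample_id)]
  herring_years <- yr[x$items$taxon == "atlantic_herring"]
  expect_true(all(herring_years >= 2013))
})

test_that("the binary era emits presence-only samples", {
  cfg <- generator_config(binary_years = c(1982:1984, 1987L))
  x <- generate_samples(cfg, seed = 2)
  era <- x$samples$year < 1990
  expect_true(all(x$samples$presence_only[era]))
  expect_false(any(x$samples$presence_only[!era]))
  binary_ids <- x$samples$sample_id[era]
  expect_true(all(is.na(
    x$items$wet_mass_g[x$items$sample_id %in% binary_ids])))
})

test_that("noise-free environmental series recover configured trends", {
  cfg <- generator_config(env = list(
    sea_ice_index = list(intercept = 19.9, slope = -0.5, sd = 0),
    temperature = list(intercept = 0.3, slope = 0.1, sd = 0)))
  env <- generate_env(cfg, seed = 1)
  tr <- trend_regression(env$sea_ice_index)
  expect_equal(tr$slope, -0.5)
  expect_equal(tr$intercept, 19.9)
  expect_equal(trend_regression(env$temperature)$slope, 0.1)
})

test_that("trend estimates are unbiased at the default noise level", {
  slopes <- vapply(1:60, function(seed) {
    trend_regression(generate_env(seed = seed)$sea_ice_index)$slope
  }, 0)
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - (-0.5)), 3 * se + 0.02)
})

test_that("the stepped population series selects a change-point form", {
  env <- generate_env(seed = 4)
  fit <- select_model(env$population_size, window = c(1996, Inf))
  expect_true(fit$form %in% c("constant_changepoint", "linear_changepoint",
                              "linear_interaction_changepoint"))
})

test_that("synthetic otoliths pair up and stay in regression range", {
  x <- generate_samples(generator_config(years = 2005:2008,
                                         samples_per_year = 15L), seed = 9)
  ot <- generate_otoliths(x, seed = 9)
  expect_true(all(ot$species %in% default_otolith_regressions()$species))
  expect_true(all(ot$otolith_mm > 0))
  out <- morphometrics_table(ot)
  # two otoliths per fish with 0.05 mm jitter: nearly all pair
  expect_lt(nrow(out), nrow(ot))
  expect_true(all(out$fish_length_mm > 0))
})
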