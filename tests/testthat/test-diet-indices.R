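test_that("frequency of occurrence matches the occurrence fraction", {
  x <- occurrence_table(879L, list(
    list(taxon = "polar_cod", n_occ = 419L, mass = 17.2),
    list(taxon = "capelin", n_occ = 107L, mass = 15.7)))
  expect_equal(round(frequency_of_occurrence(x, "polar_cod"), 1), 47.7)
  expect_equal(round(frequency_of_occurrence(x, "capelin"), 1), 12.2)
  expect_equal(frequency_of_occurrence(x, "haddock"), 0)
  expect_error(frequency_of_occurrence(x, "polar_cod", years = 1950),
               "no .*samples in scope")
})

test_that("the four metrics agree with hand computation on the toy table", {
  x <- toy_table()
  # polar cod: present in 1 of 3; masses {10, 0, 0}
  expect_equal(frequency_of_occurrence(x, "polar_cod"), 100 / 3)
  expect_equal(average_wet_weight(x, "polar_cod")$mean, 10 / 3)
  expect_equal(average_meal_mass(x, "polar_cod")$mean, 10)
  # AP: fractions 10/12, 0, 0
  expect_equal(average_mass_percentage(x, "polar_cod")$mean,
               100 * (10 / 12) / 3)
  # atlantic origin: S2 only, 8 g of 8 g total
  expect_equal(average_mass_percentage(x, "atlantic")$mean, 100 / 3)
})

test_that("meal mass excludes zeros and is an error when absent", {
  x <- occurrence_table(3L, list(
    list(taxon = "polar_cod", n_occ = 2L, mass = c(10, 20))))
  expect_equal(average_meal_mass(x, "polar_cod")$mean, 15)
  expect_error(average_meal_mass(x, "capelin"), "does not occur")
})

test_that("degenerate scopes are handled: single sample, full-mass sample", {
  x1 <- occurrence_table(1L, list(
    list(taxon = "polar_cod", n_occ = 1L, mass = 5)))
  ww <- average_wet_weight(x1, "polar_cod")
  expect_equal(ww$mean, 5)
  expect_true(is.na(ww$sem))
  expect_equal(average_mass_percentage(x1, "polar_cod")$mean, 100)
})

test_that("AP averages per-sample fractions with equal sample weight", {
  # category is 50% of one sample, 0% of the other -> AP 25%
  x <- diet_samples(
    data.frame(sample_id = c("S1", "S2"), year = 2000L),
    data.frame(sample_id = c("S1", "S1", "S2"),
               taxon = c("polar_cod", "capelin", "capelin"),
               wet_mass_g = c(5, 5, 9)))
  expect_equal(average_mass_percentage(x, "polar_cod")$mean, 25)
})

test_that("WW = MM * N / n holds exactly for every index-table row", {
  x <- generate_samples(generator_config(years = 2001:2008,
                                         samples_per_year = 25L), seed = 3)
  tab <- index_table(x)
  occ <- tab[tab$n_occ > 0, ]
  expect_equal(occ$ww_g, occ$mm_g * occ$n_occ / occ$n_samples)
  expect_true(all(tab$fo_pct >= 0 & tab$fo_pct <= 100))
  expect_true(all(tab$ap_pct >= 0 & tab$ap_pct <= 100 | is.na(tab$ap_pct)))
  expect_true(all(tab$n_occ <= tab$n_samples))
})

test_that("an empty sample can only dilute FO, WW and AP", {
  x <- toy_table()
  extra <- diet_samples(
    rbind(x$samples,
          data.frame(sample_id = "S4", year = 2005L, date = NA,
                     colony = "unknown", stage = "unknown", bird = "unknown",
                     sex = "unknown", presence_only = FALSE)),
    x$items)
  for (cat in c("polar_cod", "arctic", "atlantic")) {
    expect_lte(frequency_of_occurrence(extra, cat),
               frequency_of_occurrence(x, cat))
    expect_lte(average_wet_weight(extra, cat)$mean,
               average_wet_weight(x, cat)$mean)
  }
  expect_lte(average_mass_percentage(extra, "polar_cod")$mean,
             average_mass_percentage(x, "polar_cod")$mean)
})

test_that("FO and AP rank categories concordantly on generator output", {
  x <- generate_samples(seed = 11)
  tab <- index_table(x, categories = c(
    "polar_cod", "capelin", "atlantic_herring", "thysanoessa_inermis",
    "themisto_libellula"))
  rho <- suppressWarnings(
    cor(tab$fo_pct, tab$ap_pct, method = "spearman"))
  expect_gt(rho, 0.8)
})

test_that("annual FO series spans binary and mass eras", {
  cfg <- generator_config(years = 2004:2009, samples_per_year = 20L,
                          binary_years = 1982:1983,
                          binary_samples_per_year = 10L)
  x <- generate_samples(cfg, seed = 2)
  s <- fo_series(x, "arctic")
  expect_s3_class(s, "annual_series")
  expect_equal(series_years(s), c(1982:1983, 2004:2009))
  expect_true(all(s >= 0 & s <= 100))
  # mass metrics silently restrict to the mass era
  w <- ww_series(x, "arctic")
  expect_equal(series_years(w), 2004:2009)
})
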