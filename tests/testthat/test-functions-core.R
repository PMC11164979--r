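# arithmetic building blocks for the ecosystem-function panel

test_that("aggregate_panel averages the requested years", {
  panel <- hand_panel(c(10, 14), 2015:2016)
  expect_equal(aggregate_panel(panel)$value, 12)
  expect_equal(aggregate_panel(hand_panel(7, 2015))$value, 7)
  wide <- hand_panel(1:7, 2014:2020)
  sub <- aggregate_panel(wide, years = list(yield = 2016:2019))
  expect_equal(sub$n_years, 4)
  expect_equal(sub$value, mean(3:6))
  expect_error(aggregate_panel(hand_panel(1, 2015, fun = "nonsense")),
               "unknown ecosystem function")
})

test_that("min-max normalization maps worst to 0 and best to 1, honoring direction", {
  expect_equal(as.numeric(minmax_normalize(c(2, 4, 6))), c(0, 0.5, 1))
  expect_equal(as.numeric(minmax_normalize(c(2, 4, 6), "decreasing")),
               c(1, 0.5, 0))
  expect_error(minmax_normalize(c(5, 5, 5)), "degenerate")
  # reflection identity and range property over random vectors
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(10)
    up <- as.numeric(minmax_normalize(x))
    down <- as.numeric(minmax_normalize(x, "decreasing"))
    expect_equal(down, 1 - up)
    expect_equal(range(up), c(0, 1))
  }
})

test_that("Shannon index matches direct summation and its bounds", {
  expect_equal(shannon_index(c(10, 10)), log(2))
  expect_equal(shannon_index(42), 0)
  expect_equal(shannon_index(c(1, 2, 3)), 1.011404, tolerance = 1e-6)
  expect_error(shannon_index(c(0, 0)), "empty community")
  set.seed(1)
  for (i in 1:20) {
    counts <- rpois(sample(2:8, 1), 5) + 1
    h <- shannon_index(counts)
    expect_gte(h, 0)
    expect_lte(h, log(sum(counts > 0)) + 1e-12)
  }
  expect_equal(shannon_index(rep(7, 5)), log(5))
})

test_that("soil multidiversity is the mean proportional diversity", {
  expect_equal(soil_multidiversity(c(a = 1, b = 0.5, c = 0.2),
                                   c(a = 1, b = 1, c = 0.4)),
               mean(c(1, 0.5, 0.5)))
  expect_equal(soil_multidiversity(c(a = 2, b = 3), c(a = 2, b = 3)), 1)
  expect_equal(soil_multidiversity(c(a = 0, b = 0), c(a = 1, b = 2)), 0)
  expect_error(soil_multidiversity(c(a = 2), c(a = 1)), "inconsistent")
  # invariant to rescaling one group's (h, max) pair
  expect_equal(soil_multidiversity(c(a = 1, b = 0.6), c(a = 2, b = 0.8)),
               soil_multidiversity(c(a = 10, b = 0.6), c(a = 20, b = 0.8)))
})

test_that("composites are nested means on [0,1]", {
  expect_equal(composite_mean(c(0.2, 0.4, 0.6)), 0.4)
  expect_equal(composite_mean(c(1, 1, 1)), 1)
  expect_error(composite_mean(c(0.5, 1.2)), "0, 1")
  expect_equal(soil_health(0.6, c(0.3, 0.6, 0.9), c(0, 0.5, 1)),
               (0.6 + 0.6 + 0.5) / 3)
})

test_that("bait-lamina scoring and litterbag mass loss", {
  expect_equal(bait_lamina_consumption(rep("empty", 16)), 1)
  expect_equal(bait_lamina_consumption(rep("filled", 16)), 0)
  expect_equal(bait_lamina_consumption(c("empty", "partly", "filled",
                                         "filled")), 0.375)
  expect_error(bait_lamina_consumption(character()), "no holes")
  expect_error(bait_lamina_consumption("eaten"), "unknown hole state")
  expect_equal(litterbag_mass_loss(12, 6), 0.5)
  expect_equal(litterbag_mass_loss(12, 12), 0)
  expect_equal(litterbag_mass_loss(12, 9.6), 0.2)
  expect_error(litterbag_mass_loss(12, 12.5), "mass gain")
})

test_that("MIRR conversion and nitrogen bookkeeping", {
  expect_equal(microbial_biomass_from_mirr(1), 38)
  expect_equal(microbial_biomass_from_mirr(0), 0)
  expect_equal(microbial_biomass_from_mirr(2.5), 95)
  expect_error(microbial_biomass_from_mirr(-1), ">= 0")

  expect_equal(as.numeric(nitrogen_surplus(10, 100, 60, 5)), 55)
  expect_equal(as.numeric(nitrogen_surplus(10, 100, 60, 5,
                                           variant = "balance")), 45)
  expect_equal(as.numeric(nitrogen_surplus(0, 0, 0, 0)), 0)
  # the variants differ by exactly 2 * nmin_x1
  set.seed(3)
  for (i in 1:10) {
    a <- runif(4, 0, 100)
    d <- as.numeric(nitrogen_surplus(a[1], a[2], a[3], a[4])) -
      as.numeric(nitrogen_surplus(a[1], a[2], a[3], a[4], "balance"))
    expect_equal(d, 2 * a[4])
  }
})

test_that("unit conversions are linear and invertible", {
  expect_equal(nmin_unit_convert(1), 1000 / 270)
  expect_equal(nmin_unit_convert(0), 0)
  expect_equal(nmin_unit_convert(27), 100)
  # round trip through the inverse factor
  x <- c(0.3, 1, 5, 27)
  back <- nmin_unit_convert(x) * 0.20 * 1350 / 1000
  expect_lt(max(abs(back - x) / pmax(x, 1e-300)), 1e-12)
})

test_that("carbon stocks and fluxes from TOC percentages", {
  cs <- carbon_stock_and_flux(c("2013" = 2), 2013)
  expect_equal(cs$stock, 81)
  expect_true(is.na(cs$flux))
  cs2 <- carbon_stock_and_flux(
    c("2013" = 80 / 40.5, "2016" = 83 / 40.5), 2013)
  expect_equal(cs2$stock, c(80, 83))
  expect_equal(cs2$flux[2], 1)
  same <- carbon_stock_and_flux(c("2013" = 1.5, "2018" = 1.5), 2013)
  expect_equal(same$flux[2], 0)
  expect_error(carbon_stock_and_flux(c("2014" = 2), 2013), "baseline")
})
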