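# monetization and the natural-insurance valuation

test_that("service monetization arithmetic", {
  expect_equal(food_production_value(c(grain = 50),
                                     price_set(producer_prices = c(grain = 20))),
               1000)
  expect_equal(food_production_value(numeric(0)), 0)
  ps <- price_set("crop_+40%",
                  producer_prices = c(grain = 18, straw = 5))
  expect_equal(food_production_value(c(grain = 60, straw = 40), ps),
               (1080 + 200) * 1.4)
  expect_error(food_production_value(c(maize = 10)), "no producer price")

  expect_equal(climate_regulation_value(1, price_set()), 713.7)
  expect_equal(climate_regulation_value(0, price_set()), 0)
  expect_equal(climate_regulation_value(1, price_set("co2_90")), 329.4)
  # carbon loss is a negative value
  expect_lt(climate_regulation_value(-0.5, price_set()), 0)

  expect_equal(water_quality_value(10, price_set()), -73)
  expect_equal(water_quality_value(0, price_set()), 0)
  expect_equal(water_quality_value(10, price_set("n_1.9")), -19)
  expect_equal(water_quality_value(-5, price_set()), 0)  # no credit
})

test_that("yield series statistics", {
  expect_equal(yield_cv(c(100, 100, 100))$cv, 0)
  ys <- yield_cv(c(80, 120))
  expect_equal(ys$mean, 100)
  expect_equal(ys$cv, sqrt(800) / 100)
  expect_equal(yield_cv(3 * c(80, 120))$cv, ys$cv)  # scale invariance
  expect_error(yield_cv(100), "insufficient")
  pop <- yield_cv(c(80, 120), sd_type = "population")
  expect_equal(pop$sd, 20)
})

test_that("risk premium: closed form matches the numeric CRRA oracle", {
  expect_equal(risk_premium(100, 0, 0.28), 0)
  expect_equal(risk_premium(100, 0.5, 0), 0)
  expect_equal(risk_premium(100, 0.3, 0.28),
               100 * (1 - 1.09^(-0.14)))
  # independent oracle: certainty equivalent by numeric integration of
  # CRRA expected utility under the lognormal density
  for (case in list(c(100, 0.3, 0.28), c(250, 0.15, 0.28),
                    c(80, 0.6, 0.5))) {
    expect_equal(risk_premium(case[1], case[2], case[3]),
                 rp_oracle(case[1], case[2], case[3]), tolerance = 1e-8)
  }
  # strictly increasing in cv and r; RP/mean independent of mean
  cvs <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(risk_premium(100, cvs, 0.28)) > 0))
  rs <- seq(0.05, 2, by = 0.05)
  expect_true(all(diff(sapply(rs, function(r)
    risk_premium(100, 0.3, r))) > 0))
  expect_equal(risk_premium(1, 0.3, 0.28) * 500,
               risk_premium(500, 0.3, 0.28))
  expect_error(risk_premium(100, -0.1), ">= 0")
})

test_that("surface fitting recovers planted coefficients and matches normal equations", {
  set.seed(10)
  b <- runif(40); h <- runif(40)
  x_true <- c(10, -4, 1.5, -3, 0.5, 2)
  rp <- predict_rp(x_true, b, h)
  fit <- fit_rp_surface(b, h, rp)
  expect_equal(unname(fit$coefficients), x_true, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # constant response
  cfit <- fit_rp_surface(b, h, rep(7, 40))
  expect_equal(unname(cfit$coefficients), c(7, 0, 0, 0, 0, 0),
               tolerance = 1e-8)
  # oracle equivalence with noise, several instances
  for (i in 1:20) {
    n <- sample(8:30, 1)
    b <- runif(n); h <- runif(n); rp <- rnorm(n)
    expect_equal(unname(fit_rp_surface(b, h, rp)$coefficients),
                 normal_equations_fit(b, h, rp), tolerance = 1e-8)
  }
  expect_error(fit_rp_surface(rep(0.5, 10), runif(10), rnorm(10)),
               "collinearity")
  expect_error(fit_rp_surface(runif(5), runif(5), rnorm(5)), ">= 6")
})

test_that("insurance values: worked example and algebraic identities", {
  iv <- insurance_values(c(10, -4, 0, -3, 0, 0), b = 1, h = 1)
  expect_equal(iv$I_B, 4)
  expect_equal(iv$I_H, 3)
  expect_equal(iv$I_HB, 7)
  # no b dependence -> I_B identically 0
  flat <- insurance_values(c(5, 0, 0, -2, 1, 0), b = runif(10),
                           h = runif(10))
  expect_equal(flat$I_B, rep(0, 10))
  # decomposition identities for random surfaces
  set.seed(11)
  for (i in 1:50) {
    x <- rnorm(6, sd = 10)
    b <- runif(1); h <- runif(1)
    iv <- insurance_values(x, b, h)
    expect_equal(iv$I_HB,
                 insurance_values(x, b, 0)$I_B +
                   insurance_values(x, b, h)$I_H, tolerance = 1e-12)
    expect_equal(iv$I_HB,
                 insurance_values(x, 0, h)$I_H +
                   insurance_values(x, b, h)$I_B, tolerance = 1e-12)
  }
  expect_warning(insurance_values(c(1, 1, 1, 1, 1, 1), b = 2, h = 0.5,
                                  range_b = c(0, 1)), "outside")
})

test_that("economic totals: composition, linearity in prices", {
  comp <- data.frame(plot_id = "P1", food_production = 500,
                     climate_regulation = 713.7, water_quality = -73,
                     biodiversity_insurance = 30,
                     soil_health_insurance = 20)
  tot <- economic_totals(comp)
  expect_equal(tot$enEMF, 1190.7)
  expect_equal(tot$farmer_value, 550)
  expect_equal(tot$enEMF - tot$farmer_value,
               tot$climate_regulation + tot$water_quality)
  zero <- comp; zero[, -1] <- 0
  expect_equal(economic_totals(zero)$enEMF, 0)
  expect_error(economic_totals(comp[, -2]), "missing component")
  # doubling the CO2 price doubles the climate component exactly
  expect_equal(climate_regulation_value(1.7, price_set(co2_price = 390)),
               2 * climate_regulation_value(1.7, price_set()))
})

test_that("monetize_plots produces commensurable per-plot components", {
  d <- generate_design(10, seed = 21)
  panel <- generate_function_panel(d, sim_params(n_mainplots = 10,
                                                 seed = 21))
  ec <- monetize_plots(panel)
  expect_equal(nrow(ec), 50)
  expect_equal(ec$enEMF,
               ec$food_production + ec$climate_regulation +
                 ec$water_quality + ec$biodiversity_insurance +
                 ec$soil_health_insurance)
  expect_equal(ec$farmer_value,
               ec$food_production + ec$biodiversity_insurance +
                 ec$soil_health_insurance)
  expect_true(all(ec$water_quality <= 0))
  surf <- attr(ec, "surface")
  expect_s3_class(data.frame(), "data.frame")
  expect_length(surf$coefficients, 6)
  # the nitrogen dis-service hits intensive management hardest
  mg <- d$management[match(ec$plot_id, d$plot_id)]
  expect_lt(mean(ec$water_quality[mg == "intensive"]),
            mean(ec$water_quality[mg == "sustainable"]))
})
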