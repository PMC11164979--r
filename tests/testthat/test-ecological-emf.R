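# weighting schemes and the ecological multifunctionality index

test_that("preference transfer follows the stated allocation steps", {
  sym <- transfer_preferences(c(food_production = 25, biodiversity = 25,
                                aesthetics = 25, carbon_storage = 25))
  expect_equal(unname(sym[c("food_production", "biodiversity_conservation",
                            "soil_health", "landscape_aesthetics",
                            "climate_regulation", "water_quality")]),
               c(25, 12.5, 12.5, 25, 12.5, 12.5))
  expect_equal(sum(sym), 100)

  # the published farmer source vector: the procedure yields
  # 44/14.5/14.5/16/5.5/5.5, NOT the printed 38/18/18/14/7/7
  fa <- transfer_preferences(c(food_production = 44, biodiversity = 29,
                               aesthetics = 16, carbon_storage = 11))
  expect_equal(unname(fa["food_production"]), 44)
  expect_equal(unname(fa["biodiversity_conservation"]), 14.5)
  expect_equal(unname(fa["climate_regulation"]), 5.5)
  expect_false(isTRUE(all.equal(unname(fa["food_production"]), 38)))

  # crop/livestock averaging and mass conservation
  one <- transfer_preferences(c(food_crops = 40, livestock = 20,
                                biodiversity = 0, aesthetics = 0,
                                carbon_storage = 0))
  expect_equal(unname(one["food_production"]), 100)
  expect_error(transfer_preferences(c(biodiversity = 50, aesthetics = 50)),
               "food")
})

test_that("weighting schemes distribute service weights correctly", {
  eqf <- build_weighting_scheme("equal_function")
  expect_equal(unname(eqf$weights), rep(1 / 14, 14))
  expect_equal(sum(eqf$weights), 1)

  eqs <- build_weighting_scheme("equal_service")
  expect_equal(sum(eqs$weights), 1)
  for (f in c("nematode_diversity", "mesofauna_diversity",
              "macrofauna_diversity")) {
    expect_equal(unname(eqs$weights[[f]]), 1 / 18)
  }
  expect_equal(unname(eqs$weights[["microbial_biomass"]]), 1 / 18)
  expect_equal(unname(eqs$weights[["cellulase"]]), 1 / 54)
  expect_equal(unname(eqs$weights[["yield"]]), 1 / 6)

  # farmer fixture: printed vector sums to 102 and is renormalized
  farm <- build_weighting_scheme(
    "stakeholder", prefs = stakeholder_preferences()$farmers)
  expect_equal(sum(farm$weights), 1)
  expect_equal(unname(farm$weights[["yield"]]), 38 / 102, tolerance = 1e-12)
  expect_equal(unname(farm$weights[["flower_abundance"]]), 14 / 102,
               tolerance = 1e-12)
  expect_error(build_weighting_scheme("stakeholder"),
               "requires service preferences")
  expect_error(build_weighting_scheme(
    "stakeholder", prefs = c(food_production = 0)), "positive total")
})

test_that("egEMF is the weighted average of normalized functions", {
  plots <- paste0("P", 1:3)
  norm <- expand.grid(plot_id = plots, fun = ef_functions(),
                      stringsAsFactors = FALSE)
  names(norm)[2] <- "function"
  norm$ef <- 0.5
  norm$ef[norm$plot_id == "P1"] <- 1
  norm$ef[norm$plot_id == "P2"] <- 0
  norm$ef[norm$plot_id == "P3" & norm[["function"]] == "yield"] <- 1
  eqf <- build_weighting_scheme("equal_function")
  res <- ecological_emf(norm, eqf)
  out <- stats::setNames(res$egEMF, res$plot_id)
  expect_equal(unname(out["P1"]), 1)
  expect_equal(unname(out["P2"]), 0)
  expect_equal(unname(out["P3"]), (13 * 0.5 + 1) / 14)

  # equal_function equals the plain mean; permutation invariance
  set.seed(5)
  norm$ef <- runif(nrow(norm))
  res2 <- ecological_emf(norm, eqf)
  man <- tapply(norm$ef, norm$plot_id, mean)
  expect_equal(res2$egEMF, as.numeric(man[res2$plot_id]))
  shuf <- norm[sample(nrow(norm)), ]
  res3 <- ecological_emf(shuf, eqf)
  expect_equal(res3[order(res3$plot_id), ], res2[order(res2$plot_id), ],
               ignore_attr = TRUE)

  # missing function is reported by name
  expect_error(
    ecological_emf(norm[norm[["function"]] != "yield", ], eqf), "yield")
})

test_that("the 11-function variant renormalizes over the remaining functions", {
  keep <- setdiff(ef_functions(), c("nematode_diversity",
                                    "mesofauna_diversity",
                                    "macrofauna_diversity"))
  sub <- build_weighting_scheme("equal_function", functions = keep)
  expect_equal(length(sub$weights), 11)
  expect_equal(unname(sub$weights), rep(1 / 11, 11))
  eqs <- build_weighting_scheme("equal_service", functions = keep)
  expect_equal(sum(eqs$weights), 1)
  expect_false("nematode_diversity" %in% names(eqs$weights))
})

test_that("normalization pipeline treats nitrogen surplus as a dis-service", {
  d <- generate_design(2, seed = 2)
  panel <- generate_function_panel(d, sim_params(n_mainplots = 2, seed = 2))
  norm <- normalize_functions(aggregate_panel(panel))
  ns <- norm[norm[["function"]] == "n_surplus", ]
  expect_equal(unique(ns$direction), "decreasing")
  # the plot with the highest surplus scores 0
  agg <- aggregate_panel(panel)
  worst <- agg$plot_id[agg[["function"]] == "n_surplus"][
    which.max(agg$value[agg[["function"]] == "n_surplus"])]
  expect_equal(ns$ef[ns$plot_id == worst], 0)
  expect_true(all(norm$ef >= 0 & norm$ef <= 1))
})
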