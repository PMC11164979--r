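# synthetic-data generator: design layout, panels, images

test_that("design generation is balanced, derived columns correct and deterministic", {
  d <- generate_design(10, seed = 3)
  expect_equal(nrow(d), 50)
  expect_true(all(table(d$climate, d$lut) == 5))
  expect_true(all(table(d$mainplot_id, d$lut) == 1))
  # climate constant within mainplots
  expect_true(all(tapply(as.character(d$climate), d$mainplot_id,
                         function(x) length(unique(x))) == 1))
  # derived classifications
  expect_equal(unique(d$management[d$lut %in% c("CF", "IM")]), "intensive")
  expect_equal(unique(d$management[d$lut %in% c("EM", "EP", "OF")]),
               "sustainable")
  expect_equal(unique(d$cover[d$lut %in% c("OF", "CF")]), "cropland")
  expect_identical(d, generate_design(10, seed = 3))
  expect_false(identical(d$lut, generate_design(10, seed = 4)$lut))
  # minimal design: one replicate per cell
  d2 <- generate_design(2, seed = 1)
  expect_equal(nrow(d2), 10)
  expect_true(all(table(d2$climate, d2$lut) == 1))
})

test_that("invalid mainplot counts are rejected, balance holds for any even count", {
  expect_error(generate_design(5), "even")
  expect_error(generate_design(0), "even")
  expect_error(generate_design(-4), "even")
  for (m in c(2, 4, 8, 12)) {
    d <- generate_design(m, seed = m)
    expect_true(all(table(d$climate, d$lut) == m / 2))
  }
})

test_that("zero-noise panels recover every planted effect exactly", {
  d <- generate_design(4, seed = 2)
  p <- noiseless_params(n_mainplots = 4)
  panel <- generate_function_panel(d, p)
  agg <- aggregate_panel(panel)
  agg$climate <- d$climate[match(agg$plot_id, d$plot_id)]
  agg$management <- d$management[match(agg$plot_id, d$plot_id)]
  for (f in ef_functions()) {
    sub <- agg[agg[["function"]] == f, ]
    gm <- tapply(sub$value, list(sub$climate, sub$management), mean)
    expect_equal(gm["ambient", "sustainable"], p$baselines[[f]],
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(gm["future", "sustainable"] / gm["ambient", "sustainable"],
                 p$climate_effects[[f]], tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(gm["ambient", "intensive"] / gm["ambient", "sustainable"],
                 p$management_effects[[f]], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("Monte-Carlo mean recovery of the planted climate effect on yield", {
  d <- generate_design(200, seed = 7)
  p <- sim_params(n_mainplots = 200, climate_effects = c(yield = 0.8),
                  seed = 7)
  panel <- generate_function_panel(d, p)
  y <- panel[panel[["function"]] == "yield", ]
  y$climate <- d$climate[match(y$plot_id, d$plot_id)]
  ratio <- mean(y$value[y$climate == "future"]) /
    mean(y$value[y$climate == "ambient"])
  expect_lt(abs(ratio - 0.8), 0.02)
})

test_that("per-plot yield CV follows the planted cv model", {
  d <- generate_design(10, seed = 5)
  p <- sim_params(n_mainplots = 10, years = 1901:2000,
                  cv_model = c(0.3, -0.2, 0), seed = 5)
  panel <- generate_function_panel(d, p)
  latent <- attr(panel, "latent")
  y <- panel[panel[["function"]] == "yield", ]
  sample_cv <- tapply(y$value, y$plot_id,
                      function(v) stats::sd(v) / mean(v))
  planted <- stats::setNames(latent$cv, latent$plot_id)[names(sample_cv)]
  expect_lt(mean(abs(sample_cv - planted)), 0.04)
  expect_gt(stats::cor(sample_cv, planted), 0.7)
})

test_that("panels are deterministic given the seed and survive CSV round-trips", {
  d <- generate_design(2, seed = 1)
  p <- sim_params(n_mainplots = 2, seed = 11)
  panel <- generate_function_panel(d, p)
  expect_equal(panel, generate_function_panel(d, p))
  expect_equal(nrow(panel), 10 * length(p$years) * 14)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_function_panel(panel, tmp)
  back <- read_function_panel(tmp)
  expect_equal(back$value, panel$value)
  expect_equal(back[["function"]], panel[["function"]])
})

test_that("unknown function names in parameters are a configuration error", {
  expect_error(sim_params(baselines = c(not_a_function = 1)),
               "unknown function")
  expect_error(sim_params(cv_model = c(0.1, -0.2, 0)), "CV >= 0")
})

test_that("synthetic images carry exact pixel counts per class", {
  img <- generate_plot_image(100, 100,
                             c(red = 0.03, yellow = 0.02, white = 0.01),
                             seed = 9)
  fc <- flower_fraction(img)
  expect_equal(unname(fc$counts[c("red", "yellow", "white")]),
               c(300, 200, 100))
  expect_equal(fc$percent, 6)
  # empty request: pure background
  img0 <- generate_plot_image(20, 20, seed = 1)
  expect_equal(flower_fraction(img0)$percent, 0)
  # determinism
  expect_equal(generate_plot_image(50, 40, c(blue = 0.1), seed = 2),
               generate_plot_image(50, 40, c(blue = 0.1), seed = 2))
})

test_that("image fixture errors: bad background, bad fractions, violet", {
  expect_error(generate_plot_image(10, 10, c(red = 0.1),
                                   background = c(255, 0, 0), seed = 1),
               "fixture error")
  expect_error(generate_plot_image(10, 10, c(red = 0.7, white = 0.5)),
               "sum to at most 1")
  expect_error(generate_plot_image(10, 10, c(red = -0.1)), ">= 0")
  expect_error(generate_plot_image(10, 10, c(violet = 0.1)), "violet")
})
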