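#' Default pipeline configuration
#'
#' Builds the configuration list consumed by [run_pipeline()]: the
#' simulated design size and years, the weighting schemes and price
#' scenarios to evaluate, and the variant switches (nitrogen-surplus
#' formula, CV estimator, within-service weight distribution). Any entry
#' can be overridden; unknown entries are rejected.
#'
#' @param seed integer seed recorded in all outputs
#' @param ... overrides for the default entries
#' @return list of class `run_config`.
#' @export
#' @examples
#' cfg <- default_config(seed = 7, n_mainplots = 4)
default_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    n_mainplots = 10,
    years = 2015:2019,
    sim = list(),                      # overrides passed to sim_params()
    schemes = c("farmers", "local_residents", "conservation_agencies",
                "tourism", "equal_function", "equal_service"),
    scenarios = c("default", "co2_280", "co2_90", "n_1.9", "crop_+40%"),
    risk_aversion = 0.28,
    sd_type = "sample",
    nitrogen_variant = "literal",
    soil_health_distribution = "hierarchical",
    images = FALSE,
    image_size = 40
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with keys as in [default_config()]
#' @return a `run_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(default_config, c(list(seed = raw$seed %||% 1),
                            raw[setdiff(names(raw), "seed")]))
}

#' Per-plot soil biodiversity and soil health levels
#'
#' Computes, from an aggregated panel, the two normalized levels that
#' drive the insurance valuation: soil multidiversity `b` (mean
#' proportional Shannon diversity across the nematode, mesofauna and
#' macrofauna groups) and the soil-health composite `h` (microbial
#' biomass, enzymatic composite, decomposition composite).
#'
#' @param agg output of [aggregate_panel()]
#' @return data.frame with columns `plot_id`, `b`, `h`.
#' @export
soil_levels <- function(agg) {
  norm <- normalize_functions(agg)
  plots <- unique(agg$plot_id)
  val <- function(f, from = agg, col = "value") {
    sub <- from[from[["function"]] == f, ]
    stats::setNames(sub[[col]], sub$plot_id)[plots]
  }
  div <- vapply(ef_soil_biodiversity(), function(f) {
    v <- val(f)
    v / max(v)
  }, numeric(length(plots)))
  b <- rowMeans(div)
  nf <- function(f) val(f, from = norm, col = "ef")
  h <- vapply(seq_along(plots), function(i) {
    soil_health(nf("microbial_biomass")[i],
                c(nf("cellulase")[i], nf("nag")[i],
                  nf("acid_phosphatase")[i]),
                c(nf("bg_decomposition")[i],
                  nf("ag_decomposition_microbes")[i],
                  nf("ag_decomposition_microbes_fauna")[i]))
  }, numeric(1))
  data.frame(plot_id = plots, b = b, h = h, stringsAsFactors = FALSE)
}

#' Monetize a panel under a price scenario
#'
#' Runs the full economic valuation for every plot: mean monetary yield
#' (grassland biomass priced as grass, conventional grain as grain,
#' organically farmed grain at the organic producer price), climate
#' regulation from the mean carbon flux, the social cost of the mean
#' nitrogen surplus, and the insurance values of biodiversity and soil
#' health obtained from the risk-premium response surface fitted across
#' plots. Risk premia are computed on the monetary yield series so all
#' components share the euro/ha/yr unit.
#'
#' @param panel a `function_panel`
#' @param prices a [price_set()]
#' @param r relative risk aversion
#' @param sd_type CV estimator, `"sample"` or `"population"`
#' @param constants a [soil_constants()]
#' @return an [economic_totals()] data.frame with attributes `surface`
#'   (the fitted `rp_surface`) and `risk` (per-plot mean, cv, rp, b, h).
#' @export
monetize_plots <- function(panel, prices = price_set(), r = 0.28,
                           sd_type = "sample",
                           constants = soil_constants()) {
  agg <- aggregate_panel(panel)
  design <- unique(panel[, c("plot_id", "mainplot_id", "climate", "lut")])
  design$cover <- lut_cover(as.character(design$lut))
  plots <- unique(agg$plot_id)
  design <- design[match(plots, design$plot_id), ]

  product <- ifelse(design$cover == "grassland", "grass",
                    ifelse(design$lut == "OF", "organic_grain", "grain"))
  yield <- panel[panel[["function"]] == "yield", ]
  money_series <- lapply(seq_along(plots), function(i) {
    ys <- yield[yield$plot_id == plots[i], ]
    vapply(ys$value, function(m) {
      food_production_value(stats::setNames(m, product[i]), prices)
    }, numeric(1))
  })
  food <- vapply(money_series, mean, numeric(1))
  cvs <- vapply(money_series, function(s) yield_cv(s, sd_type)$cv,
                numeric(1))
  rp <- risk_premium(food, cvs, r)

  lv <- soil_levels(agg)
  surface <- fit_rp_surface(lv$b, lv$h, rp)
  ins <- insurance_values(surface, lv$b, lv$h,
                          range_b = range(lv$b), range_h = range(lv$h))

  pick <- function(f) {
    sub <- agg[agg[["function"]] == f, ]
    stats::setNames(sub$value, sub$plot_id)[plots]
  }
  comp <- data.frame(
    plot_id = plots,
    food_production = food,
    climate_regulation = climate_regulation_value(pick("toc_flux"), prices,
                                                  constants),
    water_quality = water_quality_value(pick("n_surplus"), prices),
    biodiversity_insurance = ins$I_B,
    soil_health_insurance = ins$I_H,
    I_HB = ins$I_HB,
    stringsAsFactors = FALSE
  )
  out <- economic_totals(comp, prices)
  attr(out, "surface") <- surface
  attr(out, "risk") <- data.frame(plot_id = plots, mean_yield = food,
                                  cv = cvs, rp = rp, b = lv$b, h = lv$h)
  out
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates simulate -> aggregate -> normalize -> ecological EMF (all
#' requested weighting schemes) -> economic EMF (all requested price
#' scenarios, including the insurance valuation) -> inference (split-plot
#' ANOVA per index, Tukey post-hoc following the interaction-first flow,
#' the biodiversity-multifunctionality regression, and the correlation
#' matrix across indices). All outputs are written as CSV files to
#' `outdir` together with a plain-text log carrying the seed, a
#' configuration hash and every constant used. Deterministic given the
#' configuration.
#'
#' @param config a `run_config` from [default_config()] or a YAML path
#' @param outdir output directory (created if needed); `NULL` writes
#'   nothing
#' @return (invisibly) a list with `design`, `panel`, `egemf`,
#'   `economic`, `anova`, `posthoc`, `regression`, `correlations`,
#'   `flowers` and `log`.
#' @export
#' @examples
#' res <- run_pipeline(default_config(seed = 1, n_mainplots = 4,
#'                                    scenarios = "default"))
#' head(res$egemf)
run_pipeline <- function(config = default_config(), outdir = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  log_lines <- c(
    sprintf("ecomult pipeline run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %d", config$seed),
    sprintf("config_hash: %s", config_hash(config)),
    constant_provenance(config)
  )

  design <- generate_design(config$n_mainplots, seed = config$seed)
  params <- do.call(sim_params, c(list(n_mainplots = config$n_mainplots,
                                       years = config$years,
                                       seed = config$seed), config$sim))
  panel <- generate_function_panel(design, params)
  agg <- aggregate_panel(panel)
  norm <- normalize_functions(agg)

  prefs <- stakeholder_preferences()
  map <- service_map(config$soil_health_distribution)
  schemes <- lapply(config$schemes, function(s) {
    if (s %in% c("equal_function", "equal_service")) {
      build_weighting_scheme(s, map = map, name = s)
    } else {
      if (!s %in% names(prefs)) {
        stop("undefined weighting scheme: ", s, call. = FALSE)
      }
      build_weighting_scheme("stakeholder", prefs = prefs[[s]], map = map,
                             name = s)
    }
  })
  egemf <- do.call(rbind, lapply(schemes, function(sc) {
    ecological_emf(norm, sc)
  }))

  economic <- do.call(rbind, lapply(config$scenarios, function(sc) {
    monetize_plots(panel, price_set(sc), r = config$risk_aversion,
                   sd_type = config$sd_type)
  }))

  # inference on every index, aligned to the design's plot order
  aligned <- function(df, col, filter_col = NULL, filter_val = NULL) {
    if (!is.null(filter_col)) df <- df[df[[filter_col]] == filter_val, ]
    stats::setNames(df[[col]], df$plot_id)[design$plot_id]
  }
  responses <- c(
    stats::setNames(lapply(config$schemes, function(s) {
      aligned(egemf, "egEMF", "scheme", s)
    }), paste0("egEMF_", config$schemes)),
    list(enEMF = aligned(economic, "enEMF", "scenario",
                         config$scenarios[1]),
         farmer_value = aligned(economic, "farmer_value", "scenario",
                                config$scenarios[1]))
  )
  anova_tables <- lapply(responses, splitplot_anova, design = design)
  posthoc <- lapply(names(responses), function(nm) {
    an <- anova_tables[[nm]]
    if (an$df_num[an$term == "subplot_residual"] <= 0) return(NULL)
    p_int <- an$p[an$term == "climate:lut"]
    term <- if (!is.na(p_int) && p_int < 0.05) "lut_climate" else "lut"
    ph <- tukey_posthoc(responses[[nm]], design, term)
    ph$term <- term
    ph
  })
  names(posthoc) <- names(responses)

  emf11 <- ecological_emf(
    norm, build_weighting_scheme(
      "equal_function",
      functions = setdiff(ef_functions(), ef_soil_biodiversity()),
      name = "equal_function_11"))
  lv <- soil_levels(agg)
  regression <- regress_biodiversity_emf(
    aligned(emf11, "egEMF"),
    stats::setNames(lv$b, lv$plot_id)[design$plot_id],
    design$climate)

  correlations <- correlation_matrix(as.data.frame(responses))

  flowers <- NULL
  if (isTRUE(config$images)) {
    fa <- aligned(agg[agg[["function"]] == "flower_abundance", ], "value")
    sz <- config$image_size
    flowers <- do.call(rbind, lapply(seq_along(fa), function(i) {
      img <- generate_plot_image(sz, sz,
                                 c(red = min(fa[i] / 100, 1)),
                                 seed = config$seed + i)
      fc <- flower_fraction(img)
      data.frame(plot_id = design$plot_id[i], true_percent = fa[i],
                 classified_percent = fc$percent,
                 stringsAsFactors = FALSE)
    }))
  }

  res <- list(design = design, panel = panel, agg = agg, norm = norm,
              egemf = egemf, economic = economic, anova = anova_tables,
              posthoc = posthoc, regression = regression,
              correlations = correlations, flowers = flowers,
              log = log_lines, config = config)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  invisible(res)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  writeLines(yaml::as.yaml(cfg[order(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}

constant_provenance <- function(config) {
  sc <- soil_constants()
  c(sprintf("constant bulk_density: %g kg/m3", sc$bulk_density),
    sprintf("constant n_mixing_depth: %g m", sc$n_mixing_depth),
    sprintf("constant c_accounting_depth: %g m", sc$c_accounting_depth),
    sprintf("constant c_to_co2: %g", sc$c_to_co2),
    sprintf("constant mirr_factor: %g", sc$mirr_factor),
    sprintf("constant risk_aversion: %g", config$risk_aversion),
    sprintf("prices default: co2 195 eur/t, n 7.30 eur/kg"),
    sprintf("nitrogen_variant: %s", config$nitrogen_variant),
    sprintf("cv estimator: %s", config$sd_type))
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  }
  ok <- FALSE
  on.exit(if (!ok) {
    unlink(list.files(outdir, full.names = TRUE))
  })
  wr(res$design, "design.csv")
  write_function_panel(res$panel, file.path(outdir, "panel.csv"))
  wr(res$egemf, "egemf.csv")
  wr(res$economic, "economic.csv")
  an <- do.call(rbind, lapply(names(res$anova), function(nm) {
    cbind(response = nm, res$anova[[nm]])
  }))
  an$stars <- significance_stars(an$p)
  wr(an, "anova.csv")
  ph <- do.call(rbind, lapply(names(res$posthoc), function(nm) {
    p <- res$posthoc[[nm]]
    if (is.null(p)) return(NULL)
    cbind(response = nm, term = p$term, p$comparisons)
  }))
  if (!is.null(ph)) wr(ph, "posthoc.csv")
  ct <- res$regression$interaction$coefficients
  wr(cbind(model = "interaction", ct), "regression.csv")
  wr(as.data.frame(res$correlations$r), "correlations.csv")
  if (!is.null(res$flowers)) wr(res$flowers, "flowers.csv")
  writeLines(res$log, file.path(outdir, "run.log"))
  ok <- TRUE
  invisible(outdir)
}
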