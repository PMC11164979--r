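#' Simulation parameters for the synthetic experiment
#'
#' Bundles everything the synthetic generator needs: per-function baseline
#' means and units, multiplicative treatment effects, relative noise
#' levels, and the model linking the yield coefficient of variation (CV)
#' to soil biodiversity `b` and soil health `h` (both on the normalized
#' \[0,1\] scale).
#'
#' Effects are multiplicative fractional changes: a future-climate effect
#' of 0.8 on yield means future plots average 80% of the ambient mean.
#' `noise_sd` entries are relative standard deviations of truncated-at-zero
#' Gaussian noise; for `yield` the entry acts as a switch (0 disables the
#' lognormal annual draw entirely, any positive value enables it with CV
#' given by `cv_model`). The defaults are illustrative magnitudes for a
#' temperate agro-experiment, not estimates from any particular dataset:
#' yields are suppressed under future climate and raised by intensive
#' management, soil biota and soil-health functions are suppressed by
#' intensive management, and nitrogen surplus is essentially an
#' intensive-management phenomenon.
#'
#' @param n_mainplots even number of mainplots
#' @param years calendar years simulated for every function
#' @param baselines named numeric, baseline mean per function (ambient,
#'   sustainable)
#' @param units named character, measurement unit per function
#' @param climate_effects named numeric, multiplicative effect of future
#'   climate per function
#' @param management_effects named numeric, multiplicative effect of
#'   intensive management per function
#' @param noise_sd named numeric, relative noise sd per function
#' @param cv_model numeric `c(intercept, b, h)`: yield CV as a linear
#'   function of soil biodiversity `b` and soil health `h`; must be
#'   nonnegative over the unit square
#' @param plot_effect_sd standard deviation (log scale) of two persistent
#'   plot-quality factors, one multiplying the three soil-biodiversity
#'   functions and one multiplying the seven soil-health functions:
#'   spatial soil heterogeneity that spreads plots continuously along the
#'   biodiversity and soil-health axes rather than clustering them at the
#'   treatment-group means. Set to 0 (together with `noise_sd`) for exact
#'   planted-effect recovery.
#' @param plot_effect_cor correlation between the two quality factors
#'   (biodiverse soils tend to be healthy soils, but the two gradients
#'   are not identical)
#' @param seed integer seed
#' @return list of class `sim_params`
#' @export
#' @examples
#' p <- sim_params(seed = 42)
#' p$cv_model
sim_params <- function(n_mainplots = 10,
                       years = 2015:2019,
                       baselines = NULL,
                       units = NULL,
                       climate_effects = NULL,
                       management_effects = NULL,
                       noise_sd = NULL,
                       cv_model = c(intercept = 0.32, b = -0.15, h = -0.10),
                       plot_effect_sd = 0.25,
                       plot_effect_cor = 0.5,
                       seed = 1) {
  funs <- ef_functions()
  def_base <- c(
    yield = 60, toc_flux = 0.8, n_surplus = 5, microbial_biomass = 300,
    cellulase = 80, nag = 50, acid_phosphatase = 120,
    bg_decomposition = 0.45, ag_decomposition_microbes = 0.30,
    ag_decomposition_microbes_fauna = 0.50,
    nematode_diversity = 2.2, mesofauna_diversity = 1.6,
    macrofauna_diversity = 1.4, flower_abundance = 3)
  def_units <- c(
    yield = "dt/ha", toc_flux = "t C/ha/yr", n_surplus = "kg N/ha",
    microbial_biomass = "ug C/g", cellulase = "nmol/h/g",
    nag = "nmol/h/g", acid_phosphatase = "nmol/h/g",
    bg_decomposition = "fraction", ag_decomposition_microbes = "fraction",
    ag_decomposition_microbes_fauna = "fraction",
    nematode_diversity = "shannon", mesofauna_diversity = "shannon",
    macrofauna_diversity = "shannon", flower_abundance = "percent")
  def_climate <- c(
    yield = 0.8, toc_flux = 0.95, n_surplus = 1.2, microbial_biomass = 0.95,
    cellulase = 0.95, nag = 0.95, acid_phosphatase = 0.95,
    bg_decomposition = 0.9, ag_decomposition_microbes = 0.85,
    ag_decomposition_microbes_fauna = 0.85,
    nematode_diversity = 0.95, mesofauna_diversity = 0.95,
    macrofauna_diversity = 0.95, flower_abundance = 0.6)
  def_mgmt <- c(
    yield = 1.3, toc_flux = 0.6, n_surplus = 8, microbial_biomass = 0.75,
    cellulase = 0.8, nag = 0.8, acid_phosphatase = 0.8,
    bg_decomposition = 0.8, ag_decomposition_microbes = 0.9,
    ag_decomposition_microbes_fauna = 0.85,
    nematode_diversity = 0.6, mesofauna_diversity = 0.7,
    macrofauna_diversity = 0.7, flower_abundance = 0.15)
  def_noise <- c(
    yield = 1, toc_flux = 0.15, n_surplus = 0.2, microbial_biomass = 0.12,
    cellulase = 0.15, nag = 0.15, acid_phosphatase = 0.15,
    bg_decomposition = 0.12, ag_decomposition_microbes = 0.12,
    ag_decomposition_microbes_fauna = 0.12,
    nematode_diversity = 0.1, mesofauna_diversity = 0.1,
    macrofauna_diversity = 0.1, flower_abundance = 0.3)

  merge_named <- function(user, def, what) {
    if (is.null(user)) return(def)
    unknown <- setdiff(names(user), funs)
    if (length(unknown)) {
      stop("configuration error: unknown function name(s) in ", what, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    def[names(user)] <- user
    def
  }
  baselines <- merge_named(baselines, def_base, "baselines")
  units_out <- def_units
  if (!is.null(units)) units_out[names(units)] <- units
  climate_effects <- merge_named(climate_effects, def_climate,
                                 "climate_effects")
  management_effects <- merge_named(management_effects, def_mgmt,
                                    "management_effects")
  noise_sd <- merge_named(noise_sd, def_noise, "noise_sd")

  if (any(baselines <= 0)) {
    stop("all baseline means must be positive", call. = FALSE)
  }
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  if (length(cv_model) != 3L || !is.numeric(cv_model)) {
    stop("cv_model must be numeric c(intercept, b, h)", call. = FALSE)
  }
  cv_model <- stats::setNames(as.numeric(cv_model), c("intercept", "b", "h"))
  corners <- expand.grid(b = 0:1, h = 0:1)
  cvs <- cv_model["intercept"] + cv_model["b"] * corners$b +
    cv_model["h"] * corners$h
  if (any(cvs < 0)) {
    stop("cv_model must give CV >= 0 over the b,h unit square",
         call. = FALSE)
  }
  stopifnot_scalar_number(plot_effect_sd, "plot_effect_sd", min = 0)
  if (abs(plot_effect_cor) > 1) {
    stop("plot_effect_cor must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(
    n_mainplots = n_mainplots, years = as.integer(years),
    baselines = baselines, units = units_out,
    climate_effects = climate_effects,
    management_effects = management_effects,
    noise_sd = noise_sd, cv_model = cv_model,
    plot_effect_sd = plot_effect_sd, plot_effect_cor = plot_effect_cor,
    seed = seed
  ), class = "sim_params")
}

# lognormal draws parameterized by arithmetic mean and CV
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sigma2 <- log1p(cv^2)
  mu <- log(mean) - sigma2 / 2
  stats::rlnorm(n, meanlog = mu, sdlog = sqrt(sigma2))
}

# truncated-at-zero Gaussian multiplicative noise, vectorized redraw
rtruncnorm_pos <- function(n, mean, sd) {
  if (all(sd == 0)) return(rep(mean, length.out = n))
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- x < 0
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean[bad], sd[bad])
  }
  x[x < 0] <- 0
  x
}

#' Generate a synthetic multi-year ecosystem-function panel
#'
#' Simulates one value per plot, year and ecosystem function. Every
#' non-yield function follows
#' `baseline * climate_effect^(future) * management_effect^(intensive)`
#' times the plot's persistent quality factor (see `plot_effect_sd` in
#' [sim_params()]), with truncated-at-zero Gaussian noise per year. Yields are drawn lognormally,
#' year by year, with an arithmetic mean given by the same product and a
#' plot-level CV given by `params$cv_model` evaluated at the plot's soil
#' multidiversity `b` and soil health `h`; those latent levels are
#' computed from the simulated soil variables exactly the way the
#' downstream analysis computes them, so the planted CV structure is
#' recoverable end to end. The realized latent table is attached as
#' `attr(panel, "latent")` (columns `plot_id`, `b`, `h`, `cv`).
#'
#' @param design a `plot_design` table from [generate_design()]
#' @param params a `sim_params` object
#' @return data.frame (class `function_panel`) with columns `plot_id`,
#'   `mainplot_id`, `climate`, `lut`, `year`, `function`, `value`, `unit`.
#' @export
#' @examples
#' d <- generate_design(2, seed = 1)
#' p <- generate_function_panel(d, sim_params(n_mainplots = 2, seed = 1))
#' nrow(p)  # 10 plots x 5 years x 14 functions
generate_function_panel <- function(design, params) {
  validate_design(design)
  if (!inherits(params, "sim_params")) {
    stop("params must be a sim_params object", call. = FALSE)
  }
  funs <- ef_functions()
  years <- params$years
  np <- nrow(design)
  future <- design$climate == "future"
  intensive <- design$management == "intensive"

  plot_mean <- function(f) {
    params$baselines[[f]] *
      params$climate_effects[[f]]^future *
      params$management_effects[[f]]^intensive
  }

  with_seed(params$seed, {
    # persistent plot-quality factors (spatial soil heterogeneity),
    # mean 1: one for the biodiversity axis, one for the soil-health
    # axis, correlated on the log scale
    if (params$plot_effect_sd > 0) {
      z1 <- stats::rnorm(np)
      z2 <- params$plot_effect_cor * z1 +
        sqrt(1 - params$plot_effect_cor^2) * stats::rnorm(np)
      sdq <- params$plot_effect_sd
      quality_b <- exp(sdq * z1 - sdq^2 / 2)
      quality_h <- exp(sdq * z2 - sdq^2 / 2)
    } else {
      quality_b <- quality_h <- rep(1, np)
    }
    bio_funs <- ef_soil_biodiversity()
    health_funs <- c("microbial_biomass", "cellulase", "nag",
                     "acid_phosphatase", "bg_decomposition",
                     "ag_decomposition_microbes",
                     "ag_decomposition_microbes_fauna")
    blocks <- lapply(setdiff(funs, "yield"), function(f) {
      quality <- if (f %in% bio_funs) {
        quality_b
      } else if (f %in% health_funs) {
        quality_h
      } else {
        1
      }
      m <- plot_mean(f) * quality
      vals <- unlist(lapply(years, function(y) {
        rtruncnorm_pos(np, m, params$noise_sd[[f]] * m)
      }))
      data.frame(plot_id = rep(design$plot_id, length(years)),
                 year = rep(years, each = np),
                 fun = f, value = vals, stringsAsFactors = FALSE)
    })
    soil <- do.call(rbind, blocks)

    latent <- .latent_levels(soil, design$plot_id)

    cv <- pmax(params$cv_model[["intercept"]] +
                 params$cv_model[["b"]] * latent$b +
                 params$cv_model[["h"]] * latent$h, 0)
    m_yield <- plot_mean("yield")
    yield_on <- params$noise_sd[["yield"]] > 0
    yv <- unlist(lapply(years, function(y) {
      if (yield_on) {
        vapply(seq_len(np), function(i) {
          rlnorm_mean_cv(1L, m_yield[i], cv[i])
        }, numeric(1))
      } else {
        m_yield
      }
    }))
    yield_block <- data.frame(plot_id = rep(design$plot_id, length(years)),
                              year = rep(years, each = np),
                              fun = "yield", value = yv,
                              stringsAsFactors = FALSE)
    long <- rbind(yield_block, soil)
    latent$cv <- cv
  })

  idx <- match(long$plot_id, design$plot_id)
  panel <- data.frame(
    plot_id = long$plot_id,
    mainplot_id = design$mainplot_id[idx],
    climate = design$climate[idx],
    lut = design$lut[idx],
    year = long$year,
    value = long$value,
    unit = unname(params$units[long$fun]),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  panel[["function"]] <- long$fun
  panel <- panel[, c("plot_id", "mainplot_id", "climate", "lut", "year",
                     "function", "value", "unit")]
  ord <- order(match(panel[["function"]], funs), panel$year, panel$plot_id)
  panel <- panel[ord, ]
  rownames(panel) <- NULL
  attr(panel, "latent") <- latent
  attr(panel, "sim_params") <- params
  class(panel) <- c("function_panel", "data.frame")
  panel
}

# latent soil multidiversity b and soil health h from a simulated long
# table of non-yield functions; mirrors the downstream composites but
# falls back to 0.5 on degenerate (zero-range) variables so that
# noise-free generator runs remain well defined
.latent_levels <- function(soil, plot_ids) {
  per_plot <- function(f) {
    sub <- soil[soil$fun == f, ]
    m <- tapply(sub$value, sub$plot_id, mean)
    as.numeric(m[plot_ids])
  }
  safe_norm <- function(x) {
    rng <- range(x)
    if (diff(rng) <= 0) return(rep(0.5, length(x)))
    (x - rng[1]) / diff(rng)
  }
  div <- vapply(ef_soil_biodiversity(), per_plot,
                numeric(length(plot_ids)))
  b <- rowMeans(sweep(div, 2, apply(div, 2, max), "/"))

  micro <- safe_norm(per_plot("microbial_biomass"))
  enz <- rowMeans(vapply(c("cellulase", "nag", "acid_phosphatase"),
                         function(f) safe_norm(per_plot(f)),
                         numeric(length(plot_ids))))
  dec <- rowMeans(vapply(c("bg_decomposition", "ag_decomposition_microbes",
                           "ag_decomposition_microbes_fauna"),
                         function(f) safe_norm(per_plot(f)),
                         numeric(length(plot_ids))))
  h <- (micro + enz + dec) / 3
  data.frame(plot_id = plot_ids, b = b, h = h, stringsAsFactors = FALSE)
}

#' Write / read a function panel as CSV
#'
#' The long-format interchange CSV has columns `plot_id`, `mainplot_id`,
#' `climate`, `lut`, `year`, `function`, `value`, `unit`.
#'
#' @param panel a `function_panel` data.frame
#' @param path file path
#' @return `read_function_panel` returns the panel data.frame;
#'   `write_function_panel` returns `path` invisibly.
#' @export
write_function_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_function_panel
#' @export
read_function_panel <- function(path) {
  panel <- utils::read.csv(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("plot_id", "mainplot_id", "climate", "lut", "year", "function",
            "value", "unit")
  miss <- setdiff(need, names(panel))
  if (length(miss)) {
    stop("panel CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  check_function_names(panel[["function"]])
  if (any(!is.finite(panel$value))) {
    stop("panel contains non-finite values", call. = FALSE)
  }
  class(panel) <- c("function_panel", "data.frame")
  panel
}

#' Generate a raster image with known flower-color ground truth
#'
#' Builds an 8-bit RGB image in which exactly `round(fraction * width *
#' height)` pixels carry the canonical representative color of each
#' requested flower class (red 255/0/0, orange 255/150/100, blue 0/0/255,
#' white 255/255/255, yellow 255/255/0) and all remaining pixels carry the
#' background color. Pixel positions are randomized under `seed`. The
#' violet class cannot be requested: no RGB triple satisfies its
#' classification rule as stated (see [classify_pixel()]).
#'
#' @param width,height image dimensions in pixels
#' @param color_fractions named numeric, e.g. `c(red = 0.07)`; fractions
#'   must be nonnegative and sum to at most 1
#' @param background RGB triple (0-255) that must not match any flower
#'   rule
#' @param seed integer seed for pixel placement
#' @return integer array `height x width x 3` with values in 0..255,
#'   class `plot_image`.
#' @export
#' @examples
#' img <- generate_plot_image(20, 20, c(red = 0.1), seed = 1)
#' flower_fraction(img)$counts[["red"]]  # 40
generate_plot_image <- function(width, height, color_fractions = numeric(),
                                background = c(0, 255, 0), seed = 1) {
  stopifnot_scalar_number(width, "width", min = 1)
  stopifnot_scalar_number(height, "height", min = 1)
  canonical <- list(red = c(255, 0, 0), orange = c(255, 150, 100),
                    blue = c(0, 0, 255), white = c(255, 255, 255),
                    yellow = c(255, 255, 0))
  if (length(color_fractions)) {
    unknown <- setdiff(names(color_fractions), names(canonical))
    if (length(unknown)) {
      stop("no canonical representative color for class(es): ",
           paste(unknown, collapse = ", "),
           if ("violet" %in% unknown) {
             " (the violet rule matches no RGB triple)"
           }, call. = FALSE)
    }
    if (any(color_fractions < 0) || sum(color_fractions) > 1) {
      stop("color fractions must be >= 0 and sum to at most 1",
           call. = FALSE)
    }
  }
  if (length(background) != 3L || any(background < 0 | background > 255)) {
    stop("background must be an RGB triple in 0..255", call. = FALSE)
  }
  if (!is.na(classify_pixel(background[1], background[2], background[3]))) {
    stop("fixture error: background color matches a flower rule and would ",
         "corrupt the ground truth", call. = FALSE)
  }
  n <- as.integer(width) * as.integer(height)
  counts <- if (length(color_fractions)) {
    round(color_fractions * n)
  } else {
    numeric(0)
  }
  if (sum(counts) > n) stop("requested fractions exceed the image size",
                            call. = FALSE)
  img <- array(0L, dim = c(height, width, 3L))
  for (k in 1:3) img[, , k] <- as.integer(background[k])
  if (sum(counts) > 0) {
    pos <- with_seed(seed, sample.int(n, sum(counts)))
    offset <- 0L
    for (cls in names(counts)) {
      if (counts[[cls]] == 0) next
      sel <- pos[(offset + 1L):(offset + counts[[cls]])]
      offset <- offset + counts[[cls]]
      col <- canonical[[cls]]
      for (k in 1:3) {
        plane <- img[, , k]
        plane[sel] <- as.integer(col[k])
        img[, , k] <- plane
      }
    }
  }
  class(img) <- c("plot_image", class(img))
  img
}
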