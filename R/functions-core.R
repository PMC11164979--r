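#' Aggregate a function panel to per-plot means
#'
#' Averages each plot's yearly measurements per ecosystem function,
#' optionally restricted to a per-function year subset (ecosystem
#' functions were measured in different years; the subset is a
#' configuration input).
#'
#' @param panel a `function_panel` data.frame
#' @param years optional named list mapping function names to the years to
#'   average over; functions not listed use all available years
#' @return data.frame with columns `plot_id`, `function`, `value` (the
#'   multi-year mean) and `n_years`.
#' @export
#' @examples
#' d <- generate_design(2, seed = 1)
#' p <- generate_function_panel(d, sim_params(n_mainplots = 2, seed = 1))
#' head(aggregate_panel(p))
aggregate_panel <- function(panel, years = NULL) {
  check_function_names(panel[["function"]])
  if (!is.null(years)) {
    check_function_names(names(years))
    keep <- rep(TRUE, nrow(panel))
    for (f in names(years)) {
      keep <- keep & (panel[["function"]] != f | panel$year %in% years[[f]])
    }
    panel <- panel[keep, ]
  }
  plots <- unique(panel$plot_id)
  funs <- unique(panel[["function"]])
  key <- interaction(panel$plot_id, panel[["function"]], drop = FALSE)
  m <- tapply(panel$value, list(panel$plot_id, panel[["function"]]), mean)
  n <- tapply(panel$value, list(panel$plot_id, panel[["function"]]), length)
  out <- expand.grid(plot_id = rownames(m), fun = colnames(m),
                     stringsAsFactors = FALSE)
  out$value <- as.vector(m)
  out$n_years <- as.vector(n)
  if (any(is.na(out$value))) {
    bad <- out[is.na(out$value), ]
    stop("missing data: no values for ",
         paste(sprintf("%s/%s", bad$plot_id, bad$fun), collapse = ", "),
         call. = FALSE)
  }
  names(out)[names(out) == "fun"] <- "function"
  rownames(out) <- NULL
  out
}

#' Min-max normalize a vector of plot-level values
#'
#' Rescales values against the minimum and maximum observed value so that
#' the worst plot scores 0 and the best scores 1. For `direction =
#' "increasing"` higher raw values are better; for `"decreasing"`
#' (dis-services such as nitrogen surplus) the scale is reflected:
#' `(max - x) / (max - min)`.
#'
#' A degenerate range (all values identical) is an error rather than a
#' silent constant, because a fabricated mid-scale value would distort any
#' weighted average built on top.
#'
#' @param x numeric vector (>= 2 distinct values)
#' @param direction `"increasing"` or `"decreasing"`
#' @return numeric vector in \[0,1\] with attributes `x_min`, `x_max`,
#'   `direction`.
#' @export
#' @examples
#' minmax_normalize(c(2, 4, 6))                 # 0.0 0.5 1.0
#' minmax_normalize(c(2, 4, 6), "decreasing")   # 1.0 0.5 0.0
minmax_normalize <- function(x, direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("values must be finite numbers", call. = FALSE)
  }
  rng <- range(x)
  if (diff(rng) <= 0) {
    stop("degenerate range: all values identical, cannot normalize",
         call. = FALSE)
  }
  ef <- if (direction == "increasing") {
    (x - rng[1]) / diff(rng)
  } else {
    (rng[2] - x) / diff(rng)
  }
  structure(ef, x_min = rng[1], x_max = rng[2], direction = direction)
}

#' Shannon diversity index
#'
#' `H = -sum(p * log(p))` over taxa with nonzero counts, with natural
#' logarithms.
#'
#' @param counts nonnegative counts (or abundances) per taxon
#' @return Shannon index, a nonnegative number.
#' @export
#' @examples
#' shannon_index(c(10, 10))  # log(2)
shannon_index <- function(counts) {
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and nonnegative", call. = FALSE)
  }
  total <- sum(counts)
  if (total <= 0) {
    stop("empty community: all counts are zero", call. = FALSE)
  }
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Soil multidiversity
#'
#' Averages, across soil organism groups, each group's Shannon diversity
#' divided by the maximum observed Shannon diversity of that group, so
#' groups with different taxonomic resolution are weighted equally.
#'
#' @param h_by_group named numeric, Shannon index per organism group
#' @param max_by_group named numeric, maximum observed Shannon index per
#'   group (same names)
#' @return soil multidiversity in \[0,1\].
#' @export
#' @examples
#' soil_multidiversity(c(nem = 1, meso = 0.5, mac = 0.2),
#'                     c(nem = 1, meso = 1, mac = 0.4))
soil_multidiversity <- function(h_by_group, max_by_group) {
  if (!length(h_by_group)) stop("no organism groups given", call. = FALSE)
  if (!setequal(names(h_by_group), names(max_by_group))) {
    stop("h_by_group and max_by_group must cover the same groups",
         call. = FALSE)
  }
  max_by_group <- max_by_group[names(h_by_group)]
  if (any(max_by_group <= 0)) {
    stop("group maxima must be positive", call. = FALSE)
  }
  if (any(h_by_group > max_by_group + 1e-12)) {
    stop("inconsistent reference: Shannon index exceeds its group maximum",
         call. = FALSE)
  }
  mean(h_by_group / max_by_group)
}

#' Mean of normalized components
#'
#' Building block for nested composites: the enzymatic composite (three
#' enzymes), the decomposition composite (three measures), and soil
#' health (microbial biomass + the two composites), each an unweighted
#' mean of components already on the \[0,1\] scale.
#'
#' @param components numeric values in \[0,1\]
#' @return their arithmetic mean.
#' @export
#' @examples
#' composite_mean(c(0.2, 0.4, 0.6))
composite_mean <- function(components) {
  if (!length(components)) stop("no components given", call. = FALSE)
  if (any(components < -1e-12) || any(components > 1 + 1e-12)) {
    stop("components must lie in [0, 1]", call. = FALSE)
  }
  mean(pmin(pmax(components, 0), 1))
}

#' Soil health composite
#'
#' Hierarchical composite: the mean of (i) normalized microbial biomass,
#' (ii) the enzymatic composite (mean of the three normalized enzyme
#' activities) and (iii) the decomposition composite (mean of the three
#' normalized decomposition rates).
#'
#' @param microbial normalized microbial biomass in \[0,1\]
#' @param enzymes three normalized enzyme activities
#' @param decomposition three normalized decomposition rates
#' @return soil health in \[0,1\].
#' @export
#' @examples
#' soil_health(0.6, c(0.3, 0.6, 0.9), c(0, 0.5, 1))  # 0.5667
soil_health <- function(microbial, enzymes, decomposition) {
  composite_mean(c(composite_mean(microbial),
                   composite_mean(enzymes),
                   composite_mean(decomposition)))
}

#' Bait-lamina consumption score
#'
#' Scores the holes of bait-lamina strips (empty = 1, partly empty = 0.5,
#' filled = 0) and returns the mean consumption, a belowground feeding
#' activity measure in \[0,1\].
#'
#' @param hole_states character vector of `"empty"`, `"partly"`, `"filled"`
#' @return mean consumption score.
#' @export
#' @examples
#' bait_lamina_consumption(c("empty", "partly", "filled", "filled"))
bait_lamina_consumption <- function(hole_states) {
  if (!length(hole_states)) stop("no holes scored", call. = FALSE)
  scores <- c(empty = 1, partly = 0.5, filled = 0)
  unknown <- setdiff(unique(hole_states), names(scores))
  if (length(unknown)) {
    stop("unknown hole state(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  mean(scores[hole_states])
}

#' Litterbag mass loss
#'
#' Fraction of the initial litter mass decomposed during the exposure
#' period. A final mass above the initial mass is flagged as an error
#' (contamination / soil ingrowth) rather than clamped.
#'
#' @param initial_mass initial dry mass, g (> 0)
#' @param final_mass recovered dry mass, g
#' @return mass-loss fraction in \[0,1\].
#' @export
#' @examples
#' litterbag_mass_loss(12, 9.6)  # 0.2
litterbag_mass_loss <- function(initial_mass, final_mass) {
  stopifnot_scalar_number(initial_mass, "initial_mass")
  stopifnot_scalar_number(final_mass, "final_mass", min = 0)
  if (initial_mass <= 0) stop("initial mass must be positive",
                              call. = FALSE)
  if (final_mass > initial_mass) {
    stop("mass gain: final mass exceeds initial mass; check the sample",
         call. = FALSE)
  }
  (initial_mass - final_mass) / initial_mass
}

#' Microbial biomass carbon from MIRR
#'
#' Converts the maximum initial respiratory response to glucose (MIRR, in
#' ul O2 / g dry soil / h) to microbial biomass carbon (ug C / g dry
#' soil) via the substrate-induced-respiration factor 38.
#'
#' @param mirr MIRR value(s), >= 0
#' @param constants a [soil_constants()] list
#' @return microbial biomass, ug C / g dry soil.
#' @export
#' @examples
#' microbial_biomass_from_mirr(1)  # 38
microbial_biomass_from_mirr <- function(mirr, constants = soil_constants()) {
  if (any(mirr < 0)) stop("MIRR must be >= 0", call. = FALSE)
  constants$mirr_factor * mirr
}

#' Plot-level nitrogen surplus
#'
#' Mineral-nitrogen bookkeeping between two consecutive pre-season dates:
#' soil mineral N at time x, plus the annual mineral-N input, minus the
#' annual N deprivation through harvest, combined with the soil mineral N
#' one year later. Two variants are provided because the sign of the
#' final term is ambiguous as commonly stated: `"literal"` (default) adds
#' the year-(x+1) soil N, `"balance"` subtracts it as a mass balance
#' would. The variant used is recorded in the result's `variant`
#' attribute. The two variants differ by exactly `2 * nmin_x1`.
#'
#' @param nmin_x soil mineral N at time x, kg N/ha
#' @param n_input annual mineral N input, kg N/ha
#' @param n_deprivation annual N removal through harvest, kg N/ha
#' @param nmin_x1 soil mineral N at time x + 1 year, kg N/ha
#' @param variant `"literal"` or `"balance"`
#' @return nitrogen surplus, kg N/ha, with attribute `variant`.
#' @export
#' @examples
#' nitrogen_surplus(10, 100, 60, 5)                       # 55
#' nitrogen_surplus(10, 100, 60, 5, variant = "balance")  # 45
nitrogen_surplus <- function(nmin_x, n_input, n_deprivation, nmin_x1,
                             variant = c("literal", "balance")) {
  variant <- match.arg(variant)
  args <- list(nmin_x = nmin_x, n_input = n_input,
               n_deprivation = n_deprivation, nmin_x1 = nmin_x1)
  for (nm in names(args)) {
    if (any(args[[nm]] < 0)) stop(nm, " must be >= 0", call. = FALSE)
  }
  out <- nmin_x + n_input - n_deprivation +
    if (variant == "literal") nmin_x1 else -nmin_x1
  structure(out, variant = variant)
}

#' Convert areal soil mineral nitrogen to a concentration
#'
#' Converts g N / m2 into mg N / kg dry soil, assuming the nitrogen mixes
#' into the upper `n_mixing_depth` (default 0.20 m) of soil with bulk
#' density `bulk_density` (default 1350 kg/m3): 1 g/m2 corresponds to
#' 1000 mg spread over 270 kg of soil, i.e. 3.7037 mg/kg.
#'
#' @param areal areal content, g N / m2 (>= 0)
#' @param constants a [soil_constants()] list
#' @return concentration, mg N / kg dry soil.
#' @export
#' @examples
#' nmin_unit_convert(27)  # 100
nmin_unit_convert <- function(areal, constants = soil_constants()) {
  if (any(areal < 0)) stop("areal N content must be >= 0", call. = FALSE)
  areal * 1000 / (constants$n_mixing_depth * constants$bulk_density)
}

#' Soil organic carbon stock and yearly flux
#'
#' Converts total organic carbon measurements (% of dry soil) into areal
#' carbon stocks, assuming the carbon pool extends to
#' `c_accounting_depth` (default 0.30 m) with bulk density
#' `bulk_density`: at the defaults one hectare holds 4050 t of soil, so
#' stock (t C/ha) = TOC% / 100 * 4050. The net yearly flux at year x is
#' the stock change since the baseline year divided by the elapsed years.
#'
#' @param toc_percent_by_year named numeric, TOC % per calendar year
#'   (names are years)
#' @param baseline_year the reference year (must be present)
#' @param constants a [soil_constants()] list
#' @return data.frame with columns `year`, `stock` (t C/ha) and `flux`
#'   (t C/ha/yr; `NA` for the baseline year).
#' @export
#' @examples
#' carbon_stock_and_flux(c("2013" = 1.9753, "2016" = 2.0494), 2013)
carbon_stock_and_flux <- function(toc_percent_by_year, baseline_year,
                                  constants = soil_constants()) {
  yrs <- as.integer(names(toc_percent_by_year))
  if (any(is.na(yrs))) {
    stop("toc_percent_by_year must be named by calendar year",
         call. = FALSE)
  }
  if (any(toc_percent_by_year < 0)) {
    stop("TOC percentages must be >= 0", call. = FALSE)
  }
  if (!(baseline_year %in% yrs)) {
    stop("baseline year ", baseline_year, " not present", call. = FALSE)
  }
  if (any(yrs < baseline_year)) {
    stop("years before the baseline are not supported", call. = FALSE)
  }
  soil_t_per_ha <- constants$c_accounting_depth * constants$bulk_density *
    10000 / 1000
  stock <- toc_percent_by_year / 100 * soil_t_per_ha
  base <- stock[[as.character(baseline_year)]]
  flux <- ifelse(yrs == baseline_year, NA_real_,
                 (stock - base) / (yrs - baseline_year))
  data.frame(year = yrs, stock = as.numeric(stock),
             flux = as.numeric(flux))
}
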