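#' Canonical ecosystem functions
#'
#' The fourteen ecosystem variables tracked by the package, in their
#' canonical order. Each variable approximates one of six ecosystem
#' services (see [service_map()]).
#'
#' @return Character vector of the 14 canonical function names.
#' @export
#' @examples
#' ef_functions()
ef_functions <- function() {
  c("yield", "toc_flux", "n_surplus", "microbial_biomass",
    "cellulase", "nag", "acid_phosphatase",
    "bg_decomposition", "ag_decomposition_microbes",
    "ag_decomposition_microbes_fauna",
    "nematode_diversity", "mesofauna_diversity", "macrofauna_diversity",
    "flower_abundance")
}

#' Canonical ecosystem services
#' @return Character vector of the six service identifiers.
#' @export
ef_services <- function() {
  c("food_production", "climate_regulation", "water_quality",
    "soil_health", "biodiversity_conservation", "landscape_aesthetics")
}

# functions whose normalization direction is "decreasing" (dis-services)
ef_decreasing <- function() "n_surplus"

# the three soil-biodiversity functions excluded from the 11-function index
ef_soil_biodiversity <- function() {
  c("nematode_diversity", "mesofauna_diversity", "macrofauna_diversity")
}

#' Map ecosystem functions to services with within-service shares
#'
#' Each canonical function indicates exactly one ecosystem service. The
#' `share` column gives the function's weight within its service under the
#' hierarchical distribution: single-function services carry share 1, the
#' three soil-biodiversity functions carry 1/3 each, and soil health is
#' hierarchical (microbial biomass 1/3; the three enzymes 1/9 each; the
#' three decomposition measures 1/9 each), mirroring the soil-health
#' composite. A flat alternative (each of the 7 soil-health functions 1/7)
#' is available via `soil_health = "flat"`.
#'
#' @param soil_health `"hierarchical"` (default) or `"flat"` within-service
#'   distribution for the seven soil-health functions.
#' @return data.frame with columns `fun`, `service`, `share`; shares sum to
#'   1 within each service.
#' @export
#' @examples
#' sm <- service_map()
#' aggregate(share ~ service, sm, sum)  # all 1
service_map <- function(soil_health = c("hierarchical", "flat")) {
  soil_health <- match.arg(soil_health)
  sh_funs <- c("microbial_biomass", "cellulase", "nag", "acid_phosphatase",
               "bg_decomposition", "ag_decomposition_microbes",
               "ag_decomposition_microbes_fauna")
  sh_share <- if (soil_health == "hierarchical") {
    c(1 / 3, rep(1 / 9, 3), rep(1 / 9, 3))
  } else {
    rep(1 / 7, 7)
  }
  out <- rbind(
    data.frame(fun = "yield", service = "food_production", share = 1),
    data.frame(fun = "toc_flux", service = "climate_regulation", share = 1),
    data.frame(fun = "n_surplus", service = "water_quality", share = 1),
    data.frame(fun = sh_funs, service = "soil_health", share = sh_share),
    data.frame(fun = ef_soil_biodiversity(),
               service = "biodiversity_conservation", share = 1 / 3),
    data.frame(fun = "flower_abundance", service = "landscape_aesthetics",
               share = 1)
  )
  rownames(out) <- NULL
  out
}

#' Physical and methodological soil constants
#'
#' Conversion constants used throughout the function calculations. All are
#' overridable, but default to the standard values: soil bulk density
#' 1350 kg/m3, mineral-nitrogen mixing depth 0.20 m, carbon accounting
#' depth 0.30 m, the molar C-to-CO2 mass factor 3.66, and the
#' substrate-induced-respiration factor 38 converting MIRR
#' (ul O2 / g dry soil / h) into microbial biomass carbon
#' (ug C / g dry soil).
#'
#' @param bulk_density soil mass per volume, kg/m3
#' @param n_mixing_depth depth over which fertiliser nitrogen mixes, m
#' @param c_accounting_depth depth of the soil carbon pool, m
#' @param c_to_co2 mass ratio CO2/C (44.009/12.011, rounded)
#' @param mirr_factor microbial biomass C per unit MIRR
#' @return Named list of class `soil_constants`.
#' @export
#' @examples
#' soil_constants()$c_to_co2
soil_constants <- function(bulk_density = 1350, n_mixing_depth = 0.20,
                           c_accounting_depth = 0.30, c_to_co2 = 3.66,
                           mirr_factor = 38) {
  vals <- list(bulk_density = bulk_density, n_mixing_depth = n_mixing_depth,
               c_accounting_depth = c_accounting_depth, c_to_co2 = c_to_co2,
               mirr_factor = mirr_factor)
  bad <- names(vals)[!vapply(vals, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, logical(1))]
  if (length(bad)) {
    stop("soil constants must be single positive numbers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(vals, class = "soil_constants")
}

# land-use type vocabulary -------------------------------------------------

lut_levels <- function() c("EM", "EP", "IM", "OF", "CF")

lut_management <- function(lut) {
  ifelse(lut %in% c("CF", "IM"), "intensive", "sustainable")
}

lut_cover <- function(lut) {
  ifelse(lut %in% c("OF", "CF"), "cropland", "grassland")
}

# internal assertions ------------------------------------------------------

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(name, " must be a single finite number", call. = FALSE)
  }
  if (x < min) stop(name, " must be >= ", min, call. = FALSE)
  invisible(x)
}

check_function_names <- function(fun) {
  unknown <- setdiff(unique(fun), ef_functions())
  if (length(unknown)) {
    stop("unknown ecosystem function name(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(fun)
}
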