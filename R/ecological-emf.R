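#' Transfer survey-based service preferences to the study's service set
#'
#' Adapts stakeholder preference percentages elicited over a source
#' survey's service set (crop food production, livestock production,
#' biodiversity, landscape aesthetics, carbon storage) to the six services
#' used here:
#'
#' 1. `food_production` = mean of crop food production and livestock
#'    production (averaged, not summed, so the provisioning service is not
#'    overweighted);
#' 2. the supporting-class weight (`biodiversity`) is multiplied by 0.5
#'    and allocated to both `biodiversity_conservation` and `soil_health`;
#' 3. the regulating-class weight (`carbon_storage`) is likewise split
#'    between `climate_regulation` and `water_quality`;
#' 4. the result is renormalized to sum to 100.
#'
#' Note that this procedure does not reproduce some published worked
#' examples of preference transfers (which appear to involve additional
#' unstated rescaling); the intermediate vector before renormalization is
#' attached as attribute `"intermediate"` so the arithmetic is auditable.
#'
#' @param original named percentages; names must include `biodiversity`,
#'   `aesthetics`, `carbon_storage` and either `food_production` or both
#'   `food_crops` and `livestock`
#' @return named numeric over the six services, summing to 100, with
#'   attribute `intermediate`.
#' @export
#' @examples
#' transfer_preferences(c(food_production = 44, biodiversity = 29,
#'                        aesthetics = 16, carbon_storage = 11))
transfer_preferences <- function(original) {
  if (any(original < 0)) {
    stop("preference percentages must be >= 0", call. = FALSE)
  }
  nm <- names(original)
  food <- if ("food_production" %in% nm) {
    original[["food_production"]]
  } else if (all(c("food_crops", "livestock") %in% nm)) {
    mean(c(original[["food_crops"]], original[["livestock"]]))
  } else {
    stop("configuration error: need food_production, or food_crops and ",
         "livestock", call. = FALSE)
  }
  need <- c("biodiversity", "aesthetics", "carbon_storage")
  miss <- setdiff(need, nm)
  if (length(miss)) {
    stop("configuration error: missing source service(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  inter <- c(
    food_production = food,
    biodiversity_conservation = 0.5 * original[["biodiversity"]],
    soil_health = 0.5 * original[["biodiversity"]],
    landscape_aesthetics = original[["aesthetics"]],
    climate_regulation = 0.5 * original[["carbon_storage"]],
    water_quality = 0.5 * original[["carbon_storage"]]
  )
  if (sum(inter) <= 0) {
    stop("configuration error: preferences sum to zero", call. = FALSE)
  }
  out <- inter / sum(inter) * 100
  attr(out, "intermediate") <- inter
  out
}

#' Stakeholder service-preference fixtures
#'
#' Named preference vectors (percent per service) for the four stakeholder
#' groups. The `farmers` vector is the published final weighting (38%
#' food production, 18% each for biodiversity conservation and soil
#' health, 14% landscape aesthetics, 7% each for climate regulation and
#' water quality); note it sums to 102% and is renormalized when turned
#' into a weighting scheme. `farmers_low_regulating` is an alternative
#' reading under which farmers assign only 5% in total to the regulating
#' and supporting services. The vectors for local residents, conservation
#' agencies and the tourism sector are synthetic illustrative defaults
#' consistent with the qualitative pattern (residents: high food and
#' aesthetics; conservation agencies: high supporting/regulating; tourism:
#' highest aesthetics); they are configuration defaults, not survey
#' results.
#'
#' @return named list of preference vectors over [ef_services()].
#' @export
#' @examples
#' stakeholder_preferences()$farmers
stakeholder_preferences <- function() {
  v <- function(food, climate, water, soil, bio, aest) {
    c(food_production = food, climate_regulation = climate,
      water_quality = water, soil_health = soil,
      biodiversity_conservation = bio, landscape_aesthetics = aest)
  }
  list(
    farmers = v(38, 7, 7, 18, 18, 14),
    farmers_low_regulating = v(95 * 38 / 52, 1.25, 1.25, 1.25, 1.25,
                               95 * 14 / 52),
    local_residents = v(30, 8, 8, 12, 12, 30),
    conservation_agencies = v(10, 17, 17, 24, 24, 8),
    tourism = v(15, 10, 11, 12, 12, 40)
  )
}

#' Build a weighting scheme over ecosystem functions
#'
#' Produces the per-function weights `alpha_i` used by the ecological
#' multifunctionality index:
#'
#' * `equal_function`: every included function gets `1/N`;
#' * `equal_service`: every service represented among the included
#'   functions gets an equal share, distributed within the service by the
#'   `share` column of the service map (e.g. with all 14 functions each
#'   service gets 1/6 and each of the three soil-biodiversity functions
#'   gets 1/18);
#' * `stakeholder`: service weights from `prefs` (renormalized to 1 over
#'   the represented services), distributed within services the same way.
#'
#' @param kind `"stakeholder"`, `"equal_function"` or `"equal_service"`
#' @param prefs named service percentages (required for `stakeholder`)
#' @param map a [service_map()] data.frame
#' @param functions the functions to include (default all 14); weights are
#'   renormalized over this subset
#' @param name scheme label stored in results
#' @return list of class `weighting_scheme` with elements `name`, `kind`
#'   and `weights` (named numeric summing to 1).
#' @export
#' @examples
#' build_weighting_scheme("equal_service")$weights[["nematode_diversity"]]
build_weighting_scheme <- function(kind = c("stakeholder", "equal_function",
                                            "equal_service"),
                                   prefs = NULL, map = service_map(),
                                   functions = ef_functions(),
                                   name = NULL) {
  kind <- match.arg(kind)
  check_function_names(functions)
  map <- map[map$fun %in% functions, ]
  if (kind == "equal_function") {
    w <- stats::setNames(rep(1 / length(functions), length(functions)),
                         functions)
  } else {
    sv <- if (kind == "equal_service") {
      svs <- unique(map$service)
      stats::setNames(rep(1, length(svs)), svs)
    } else {
      if (is.null(prefs)) {
        stop("stakeholder scheme requires service preferences",
             call. = FALSE)
      }
      prefs[names(prefs) %in% unique(map$service)]
    }
    if (sum(sv) <= 0) {
      stop("configuration error: preferences must sum to a positive total",
           call. = FALSE)
    }
    sv <- sv / sum(sv)
    # within-service shares renormalized over the included functions
    w <- stats::setNames(numeric(length(map$fun)), map$fun)
    for (s in names(sv)) {
      rows <- map$service == s
      w[map$fun[rows]] <- sv[[s]] * map$share[rows] / sum(map$share[rows])
    }
    w <- w[functions[functions %in% names(w)]]
  }
  structure(list(name = name %||% kind, kind = kind, weights = w),
            class = "weighting_scheme")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a per-plot function table
#'
#' Applies [minmax_normalize()] per ecosystem function over all plots
#' (pooled across climates and land-use types), using direction
#' `"decreasing"` for the dis-service nitrogen surplus and `"increasing"`
#' for every other function, so all normalized values point "more is
#' better".
#'
#' @param agg output of [aggregate_panel()]
#' @param directions optional named character overriding the direction per
#'   function
#' @return data.frame with columns `plot_id`, `function`, `ef`,
#'   `direction`, `x_min`, `x_max`.
#' @export
normalize_functions <- function(agg, directions = NULL) {
  check_function_names(agg[["function"]])
  funs <- unique(agg[["function"]])
  dir_map <- stats::setNames(
    ifelse(funs %in% ef_decreasing(), "decreasing", "increasing"), funs)
  if (!is.null(directions)) dir_map[names(directions)] <- directions
  out <- lapply(funs, function(f) {
    sub <- agg[agg[["function"]] == f, ]
    ef <- minmax_normalize(sub$value, dir_map[[f]])
    data.frame(plot_id = sub$plot_id, fun = f, ef = as.numeric(ef),
               direction = dir_map[[f]],
               x_min = attr(ef, "x_min"), x_max = attr(ef, "x_max"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  names(out)[names(out) == "fun"] <- "function"
  out
}

#' Ecological ecosystem multifunctionality (egEMF)
#'
#' The weighted average `egEMF = sum_i alpha_i * EF_i` of the normalized
#' ecosystem-function levels of a plot, with weights from a
#' [build_weighting_scheme()]. Because every `EF_i` lies in \[0,1\] and
#' the weights sum to 1, egEMF lies in \[0,1\].
#'
#' @param normalized output of [normalize_functions()]
#' @param scheme a `weighting_scheme`
#' @return data.frame with columns `plot_id`, `scheme`, `egEMF`.
#' @export
ecological_emf <- function(normalized, scheme) {
  if (!inherits(scheme, "weighting_scheme")) {
    stop("scheme must be a weighting_scheme", call. = FALSE)
  }
  w <- scheme$weights
  if (abs(sum(w) - 1) > 1e-9 || any(w < 0)) {
    stop("scheme weights must be nonnegative and sum to 1", call. = FALSE)
  }
  plots <- unique(normalized$plot_id)
  sub <- normalized[normalized[["function"]] %in% names(w), ]
  counts <- table(sub$plot_id)
  if (any(counts != length(w)) || !setequal(names(counts), plots)) {
    have <- tapply(sub[["function"]], sub$plot_id, identity,
                   simplify = FALSE)
    missing <- unique(unlist(lapply(have, function(f) setdiff(names(w), f))))
    stop("missing normalized value(s) for function(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  alpha <- w[sub[["function"]]]
  emf <- tapply(alpha * sub$ef, sub$plot_id, sum)
  data.frame(plot_id = names(emf), scheme = scheme$name,
             egEMF = as.numeric(emf), row.names = NULL,
             stringsAsFactors = FALSE)
}
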