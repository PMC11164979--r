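#' Accounting prices and scenarios
#'
#' A price set carries the accounting prices used to monetize ecosystem
#' services: producer prices per harvested product (euro/dt), the social
#' cost of CO2 (default 195 euro/t, the German Federal Environmental
#' Agency recommendation), the social cost of reactive-nitrogen surplus
#' leaching into surface water (default 7.30 euro/kg N), and a crop-price
#' multiplier for sensitivity runs. Named scenarios mirror the published
#' sensitivity analysis: `co2_280` (higher social cost of carbon),
#' `co2_90` (ETS 2021 market price), `n_1.9` (groundwater leaching
#' accounting price) and `crop_+40%`.
#'
#' The default producer prices are documented placeholders (supplementary
#' price tables are not part of this package); override them with real
#' prices for any serious valuation.
#'
#' @param scenario one of `"default"`, `"co2_280"`, `"co2_90"`, `"n_1.9"`,
#'   `"crop_+40%"`
#' @param producer_prices named euro/dt prices per product
#' @param co2_price euro per t CO2
#' @param n_price euro per kg N surplus
#' @param crop_price_multiplier multiplier on producer prices
#' @return list of class `price_set`.
#' @export
#' @examples
#' price_set("co2_90")$co2_price  # 90
price_set <- function(scenario = c("default", "co2_280", "co2_90", "n_1.9",
                                   "crop_+40%"),
                      producer_prices = c(grain = 18, straw = 5,
                                          grass = 9, organic_grain = 25),
                      co2_price = 195, n_price = 7.30,
                      crop_price_multiplier = 1) {
  scenario <- match.arg(scenario)
  switch(scenario,
         "co2_280" = co2_price <- 280,
         "co2_90" = co2_price <- 90,
         "n_1.9" = n_price <- 1.9,
         "crop_+40%" = crop_price_multiplier <- 1.4,
         NULL)
  if (any(producer_prices < 0) || co2_price < 0 || n_price < 0 ||
      crop_price_multiplier < 0) {
    stop("prices must be >= 0", call. = FALSE)
  }
  structure(list(scenario = scenario, producer_prices = producer_prices,
                 co2_price = co2_price, n_price = n_price,
                 crop_price_multiplier = crop_price_multiplier),
            class = "price_set")
}

#' Market value of food production
#'
#' Multiplies each harvested mass (dt/ha) by its producer price and the
#' crop-price multiplier, and sums over products (grain and straw are
#' priced separately for crops; all cuts are summed for grassland).
#'
#' @param masses named dt/ha per product
#' @param prices a [price_set()]
#' @return euro/ha.
#' @export
#' @examples
#' food_production_value(c(grain = 50), price_set())  # 900
food_production_value <- function(masses, prices = price_set()) {
  if (any(masses < 0)) stop("masses must be >= 0", call. = FALSE)
  unpriced <- setdiff(names(masses), names(prices$producer_prices))
  if (length(unpriced)) {
    stop("configuration error: no producer price for: ",
         paste(unpriced, collapse = ", "), call. = FALSE)
  }
  sum(masses * prices$producer_prices[names(masses)]) *
    prices$crop_price_multiplier
}

#' Value of climate regulation from the soil carbon flux
#'
#' Net carbon flux (t C/ha/yr, negative for carbon loss) times the
#' C-to-CO2 mass factor 3.66 times the CO2 accounting price.
#'
#' @param c_flux t C/ha/yr
#' @param prices a [price_set()]
#' @param constants a [soil_constants()]
#' @return euro/ha/yr (negative if the soil loses carbon).
#' @export
#' @examples
#' climate_regulation_value(1, price_set())  # 713.7
climate_regulation_value <- function(c_flux, prices = price_set(),
                                     constants = soil_constants()) {
  c_flux * constants$c_to_co2 * prices$co2_price
}

#' Social cost of nitrogen surplus (water quality)
#'
#' A positive nitrogen surplus is monetized as a damage:
#' `-surplus * n_price`. Zero or negative surplus contributes zero (no
#' credit for a nitrogen deficit).
#'
#' @param n_surplus kg N/ha/yr
#' @param prices a [price_set()]
#' @return euro/ha/yr, always <= 0.
#' @export
#' @examples
#' water_quality_value(10, price_set())  # -73
water_quality_value <- function(n_surplus, prices = price_set()) {
  -pmax(n_surplus, 0) * prices$n_price
}

#' Mean and coefficient of variation of a yield series
#'
#' @param series annual (monetary) yields, length >= 2
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`
#' @return list of class `yield_series` with `mean`, `sd`, `cv`, `n`.
#' @export
#' @examples
#' yield_cv(c(80, 120))$cv  # 0.2828
yield_cv <- function(series, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(series) < 2L) {
    stop("insufficient data: need >= 2 years for a CV", call. = FALSE)
  }
  m <- mean(series)
  s <- stats::sd(series)
  if (sd_type == "population") {
    s <- s * sqrt((length(series) - 1) / length(series))
  }
  structure(list(mean = m, sd = s, cv = s / m, n = length(series)),
            class = "yield_series")
}

#' Risk premium of a stochastic yield under CRRA preferences
#'
#' For a lognormally distributed yield with arithmetic mean `mean_y` and
#' coefficient of variation `cv`, and a farmer with constant relative risk
#' aversion `r`, the certainty equivalent is
#' `mean_y * (1 + cv^2)^(-r/2)` and the risk premium is the mean minus
#' the certainty equivalent:
#'
#' `RP = mean_y * (1 - (1 + cv^2)^(-r/2))`
#'
#' RP is zero at `cv = 0` or `r = 0` and strictly increasing in both for a
#' positive mean; `RP/mean_y` does not depend on the mean. The default
#' risk aversion 0.28 corresponds to a slightly risk-averse farmer.
#'
#' @param mean_y mean yield (euro/ha), >= 0
#' @param cv coefficient of variation, >= 0
#' @param r relative risk aversion, >= 0 (default 0.28)
#' @return risk premium, same unit as `mean_y`.
#' @export
#' @examples
#' risk_premium(100, 0.3)  # 1.199
risk_premium <- function(mean_y, cv, r = 0.28) {
  if (any(mean_y < 0)) stop("mean yield must be >= 0", call. = FALSE)
  if (any(cv < 0)) stop("CV must be >= 0", call. = FALSE)
  if (any(r < 0)) stop("risk aversion must be >= 0", call. = FALSE)
  mean_y * (1 - (1 + cv^2)^(-r / 2))
}

#' Fit the quadratic risk-premium response surface
#'
#' Least-squares fit of
#' `RP(b, h) = x1 + x2 b + x3 b^2 + x4 h + x5 h^2 + x6 b h`
#' to per-plot risk premia as a function of soil biodiversity `b` and soil
#' health `h` (both on the normalized \[0,1\] scale).
#'
#' @param b,h,rp numeric vectors of equal length (>= 6 observations)
#' @return list of class `rp_surface` with `coefficients` (x1..x6),
#'   `r_squared`, `sigma` and `n`.
#' @export
#' @examples
#' s <- fit_rp_surface(b = runif(20), h = runif(20), rp = runif(20))
#' s$coefficients
fit_rp_surface <- function(b, h, rp) {
  n <- length(rp)
  if (length(b) != n || length(h) != n) {
    stop("b, h and rp must have equal length", call. = FALSE)
  }
  if (n < 6L) stop("need >= 6 observations to fit the surface",
                   call. = FALSE)
  X <- cbind(1, b, b^2, h, h^2, b * h)
  if (qr(X)$rank < 6L) {
    stop("collinearity: the (b, h) design does not identify all six ",
         "surface coefficients", call. = FALSE)
  }
  fit <- stats::lm.fit(X, rp)
  coefs <- stats::setNames(fit$coefficients, paste0("x", 1:6))
  resid <- fit$residuals
  ss_res <- sum(resid^2)
  ss_tot <- sum((rp - mean(rp))^2)
  structure(list(coefficients = coefs,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 sigma = sqrt(ss_res / max(n - 6, 1)), n = n),
            class = "rp_surface")
}

#' Evaluate a fitted risk-premium surface
#'
#' @param surface an `rp_surface` (or a plain numeric vector x1..x6)
#' @param b,h evaluation points
#' @return predicted risk premium.
#' @export
predict_rp <- function(surface, b, h) {
  x <- if (inherits(surface, "rp_surface")) surface$coefficients else surface
  if (length(x) != 6L) stop("surface needs six coefficients", call. = FALSE)
  x[1] + x[2] * b + x[3] * b^2 + x[4] * h + x[5] * h^2 + x[6] * b * h
}

#' Natural insurance values of biodiversity and soil health
#'
#' From a fitted risk-premium surface, the insurance value of biodiversity
#' at levels `(b, h)` is the risk-premium reduction attributable to
#' biodiversity, `I_B = RP(0, h) - RP(b, h)`; the insurance value of soil
#' health is `I_H = RP(b, 0) - RP(b, h)`; and the joint value is
#' `I_HB = RP(0, 0) - RP(b, h)`. These satisfy the exact decomposition
#' identities `I_HB(b, h) = I_B(b, 0) + I_H(b, h) = I_H(0, h) + I_B(b, h)`.
#' Evaluation points outside the fitted data's range are flagged with a
#' warning (the quadratic surface extrapolates poorly).
#'
#' @param surface an `rp_surface` from [fit_rp_surface()] or a numeric
#'   vector x1..x6
#' @param b,h evaluation levels (vectorized)
#' @param range_b,range_h optional fitted ranges used for the
#'   extrapolation warning
#' @return data.frame with columns `b`, `h`, `I_B`, `I_H`, `I_HB`
#'   (euro/ha).
#' @export
#' @examples
#' insurance_values(c(10, -4, 0, -3, 0, 0), b = 1, h = 1)
insurance_values <- function(surface, b, h, range_b = NULL,
                             range_h = NULL) {
  if (!is.null(range_b) &&
      any(b < range_b[1] - 1e-9 | b > range_b[2] + 1e-9)) {
    warning("evaluating the surface outside the fitted biodiversity range")
  }
  if (!is.null(range_h) &&
      any(h < range_h[1] - 1e-9 | h > range_h[2] + 1e-9)) {
    warning("evaluating the surface outside the fitted soil-health range")
  }
  rp_bh <- predict_rp(surface, b, h)
  data.frame(
    b = b, h = h,
    I_B = predict_rp(surface, 0, h) - rp_bh,
    I_H = predict_rp(surface, b, 0) - rp_bh,
    I_HB = predict_rp(surface, 0, 0) - rp_bh
  )
}

#' Economic ecosystem multifunctionality (enEMF)
#'
#' Sums the monetary values of the assessed ecosystem services per plot:
#' `enEMF = food + climate + water + I_B + I_H` (landscape aesthetics is
#' not monetized). The farmer's value is the subset the farmer directly
#' receives: food production plus the two insurance values.
#'
#' @param components data.frame with columns `plot_id`,
#'   `food_production`, `climate_regulation`, `water_quality`,
#'   `biodiversity_insurance`, `soil_health_insurance` (euro/ha/yr);
#'   an `I_HB` column, if present, is carried through
#' @param prices the [price_set()] used (recorded in the output)
#' @return data.frame with the components, `enEMF`, `farmer_value` and
#'   `scenario`.
#' @export
economic_totals <- function(components, prices = price_set()) {
  need <- c("plot_id", "food_production", "climate_regulation",
            "water_quality", "biodiversity_insurance",
            "soil_health_insurance")
  miss <- setdiff(need, names(components))
  if (length(miss)) {
    stop("missing component(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- components
  out$enEMF <- with(components, food_production + climate_regulation +
                      water_quality + biodiversity_insurance +
                      soil_health_insurance)
  out$farmer_value <- with(components, food_production +
                             biodiversity_insurance +
                             soil_health_insurance)
  out$scenario <- prices$scenario
  out
}
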