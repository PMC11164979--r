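# shared fixtures built in code

# a minimal balanced design (2 mainplots, 10 plots)
tiny_design <- function(seed = 1) generate_design(2, seed = seed)

# simulation parameters with all stochastic components switched off
noiseless_params <- function(n_mainplots = 2, years = 2015:2016, ...) {
  sim_params(n_mainplots = n_mainplots, years = years,
             noise_sd = stats::setNames(rep(0, 14), ef_functions()),
             plot_effect_sd = 0, ...)
}

# a tiny long-format panel built by hand (one function, two plots)
hand_panel <- function(values, years, plot_id = "P1", fun = "yield") {
  df <- data.frame(plot_id = plot_id, mainplot_id = "MP01",
                   climate = "ambient", lut = "EM",
                   year = years, value = values,
                   unit = "dt/ha", stringsAsFactors = FALSE,
                   check.names = FALSE)
  df[["function"]] <- fun
  df[, c("plot_id", "mainplot_id", "climate", "lut", "year", "function",
         "value", "unit")]
}

# independent certainty-equivalent oracle: numeric integration of the
# CRRA expected utility of a lognormal yield with given mean and CV
rp_oracle <- function(mean_y, cv, r) {
  sigma2 <- log1p(cv^2)
  mu <- log(mean_y) - sigma2 / 2
  e_y1r <- stats::integrate(function(y) {
    y^(1 - r) * stats::dlnorm(y, mu, sqrt(sigma2))
  }, 0, Inf, rel.tol = 1e-12)$value
  mean_y - e_y1r^(1 / (1 - r))
}

# brute-force least squares for the quadratic risk-premium surface
normal_equations_fit <- function(b, h, rp) {
  X <- cbind(1, b, b^2, h, h^2, b * h)
  as.numeric(solve(crossprod(X), crossprod(X, rp)))
}
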