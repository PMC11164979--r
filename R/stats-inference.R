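#' Split-plot ANOVA for the balanced two-factor design
#'
#' Classical stratified sums-of-squares F tests for a balanced split-plot
#' design: climate (the whole-plot factor) is tested against the
#' mainplot-within-climate error with `df = (1, m - 2)` for `m`
#' mainplots; land-use type and the climate x land-use interaction (the
#' subplot factors) are tested against the subplot residual with
#' `df = (t - 1, (m - 2)(t - 1))` for `t` land-use types. In the balanced
#' complete case these F tests coincide exactly with the REML
#' mixed-model/Satterthwaite tests (mainplot nested in climate as a
#' random effect). Unbalanced designs are rejected rather than
#' approximated.
#'
#' @param response numeric vector, one value per row of `design`
#' @param design a `plot_design` table
#' @return data.frame of class `anova_table` with columns `term`,
#'   `stratum`, `df_num`, `df_den`, `ss`, `ms`, `F`, `p` (plus residual
#'   rows with `NA` F). Degenerate responses (zero residual variance)
#'   yield `NA` F and p with attribute `degenerate = TRUE`.
#' @export
#' @examples
#' d <- generate_design(10, seed = 1)
#' y <- rnorm(50)
#' splitplot_anova(y, d)
splitplot_anova <- function(response, design) {
  validate_design(design)
  if (length(response) != nrow(design) || any(!is.finite(response))) {
    stop("response must be finite with one value per plot", call. = FALSE)
  }
  tab <- table(design$mainplot_id, design$lut)
  if (!all(tab == 1L)) {
    stop("unsupported design: split-plot ANOVA requires the balanced ",
         "complete layout", call. = FALSE)
  }
  y <- response
  mp <- as.character(design$mainplot_id)
  cl <- as.character(design$climate)
  lut <- as.character(design$lut)
  m <- length(unique(mp))
  t <- length(unique(lut))
  grand <- mean(y)

  mean_by <- function(g) tapply(y, g, mean)
  cl_mean <- mean_by(cl)
  mp_mean <- mean_by(mp)
  lut_mean <- mean_by(lut)
  cell_mean <- tapply(y, list(cl, lut), mean)

  mp_climate <- tapply(cl, mp, `[`, 1L)

  ss_climate <- t * (m / 2) * sum((cl_mean - grand)^2)
  ss_mainplot <- t * sum((mp_mean - cl_mean[mp_climate])^2)
  ss_lut <- m * sum((lut_mean - grand)^2)
  dev_cell <- sweep(sweep(cell_mean, 1, cl_mean - grand), 2, lut_mean)
  ss_int <- (m / 2) * sum(dev_cell^2)
  ss_tot <- sum((y - grand)^2)
  ss_res <- ss_tot - ss_climate - ss_mainplot - ss_lut - ss_int

  df_mp <- m - 2
  df_res <- (m - 2) * (t - 1)
  ms_mp <- ss_mainplot / df_mp
  ms_res <- ss_res / df_res

  degenerate <- !is.finite(ms_res) || !is.finite(ms_mp) ||
    ms_res <= .Machine$double.eps * max(abs(y), 1)^2 ||
    ms_mp <= .Machine$double.eps * max(abs(y), 1)^2
  safe_f <- function(ms_num, ms_den, df1, df2) {
    if (df2 <= 0 || !is.finite(ms_den) ||
        ms_den <= .Machine$double.eps * max(abs(y), 1)^2) {
      return(c(NA_real_, NA_real_))
    }
    f <- ms_num / ms_den
    c(f, stats::pf(f, df1, df2, lower.tail = FALSE))
  }
  f_cl <- safe_f(ss_climate / 1, ms_mp, 1, df_mp)
  f_lut <- safe_f(ss_lut / (t - 1), ms_res, t - 1, df_res)
  f_int <- safe_f(ss_int / (t - 1), ms_res, t - 1, df_res)

  out <- data.frame(
    term = c("climate", "mainplot_error", "lut", "climate:lut",
             "subplot_residual"),
    stratum = c("mainplot", "mainplot", "subplot", "subplot", "subplot"),
    df_num = c(1, df_mp, t - 1, t - 1, df_res),
    df_den = c(df_mp, NA, df_res, df_res, NA),
    ss = c(ss_climate, ss_mainplot, ss_lut, ss_int, ss_res),
    ms = c(ss_climate, ms_mp, ss_lut / (t - 1), ss_int / (t - 1), ms_res),
    F = c(f_cl[1], NA, f_lut[1], f_int[1], NA),
    p = c(f_cl[2], NA, f_lut[2], f_int[2], NA),
    stringsAsFactors = FALSE
  )
  attr(out, "degenerate") <- degenerate
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Tukey post-hoc comparisons after a split-plot ANOVA
#'
#' Estimated marginal means for land-use types (or climate x land-use
#' cells, when the interaction is significant) with pairwise comparisons
#' adjusted by the studentized-range (Tukey HSD) method, using the
#' subplot residual mean square and its degrees of freedom. With only two
#' means the Tukey-adjusted p equals the unadjusted two-sided t-test p.
#'
#' @param response numeric vector, one value per row of `design`
#' @param design a `plot_design` table
#' @param term `"lut"` or `"lut_climate"`
#' @return list with `means` (per-level estimated marginal means) and
#'   `comparisons` (pair, estimate, se, t, p_unadjusted, p_adjusted).
#' @export
tukey_posthoc <- function(response, design,
                          term = c("lut", "lut_climate")) {
  term <- match.arg(term)
  an <- splitplot_anova(response, design)
  ms_res <- an$ms[an$term == "subplot_residual"]
  df_res <- an$df_num[an$term == "subplot_residual"]
  if (df_res <= 0 || !is.finite(ms_res)) {
    stop("no subplot residual degrees of freedom: post-hoc comparisons ",
         "need more than 2 mainplots", call. = FALSE)
  }
  groups <- if (term == "lut") {
    as.character(design$lut)
  } else {
    paste(design$lut, design$climate, sep = ":")
  }
  means <- tapply(response, groups, mean)
  ns <- tapply(response, groups, length)
  k <- length(means)
  if (k < 2L) stop("need at least 2 levels to compare", call. = FALSE)
  pairs <- utils::combn(names(means), 2)
  est <- means[pairs[1, ]] - means[pairs[2, ]]
  se <- sqrt(ms_res * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
  tstat <- est / se
  p_un <- 2 * stats::pt(abs(tstat), df_res, lower.tail = FALSE)
  p_adj <- stats::ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df_res,
                         lower.tail = FALSE)
  list(
    means = data.frame(level = names(means), emmean = as.numeric(means),
                       n = as.numeric(ns),
                       se = sqrt(ms_res / as.numeric(ns)),
                       stringsAsFactors = FALSE),
    comparisons = data.frame(
      pair = paste(pairs[1, ], pairs[2, ], sep = " - "),
      estimate = as.numeric(est), se = as.numeric(se),
      t = as.numeric(tstat), df = df_res,
      p_unadjusted = as.numeric(p_un),
      p_adjusted = pmin(as.numeric(p_adj), 1),
      stringsAsFactors = FALSE
    )
  )
}

#' Biodiversity-multifunctionality regressions
#'
#' Relates an 11-function multifunctionality index (soil-biodiversity
#' functions excluded, so predictor and response share no components) to
#' soil multidiversity: a pooled fit, separate fits per climate, and an
#' interaction model `emf11 ~ multidiv * climate` whose interaction
#' coefficient tests whether the biodiversity-multifunctionality slope
#' differs between climates.
#'
#' @param emf11 per-plot 11-function equal-weight multifunctionality
#' @param multidiv per-plot soil multidiversity
#' @param climate factor with two levels, one per plot
#' @return list of class `biodiv_emf_fits` with elements `pooled`,
#'   `per_climate` (a list per level) and `interaction`; each a list with
#'   `coefficients` (estimate, se, t, p) and `r_squared`.
#' @export
regress_biodiversity_emf <- function(emf11, multidiv, climate) {
  if (stats::var(multidiv) == 0) {
    stop("degenerate fit: constant predictor", call. = FALSE)
  }
  climate <- factor(climate)
  tidy_fit <- function(fit) {
    s <- summary(fit)
    ct <- s$coefficients
    list(coefficients = data.frame(
      term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
      t = ct[, 3], p = ct[, 4], row.names = NULL,
      stringsAsFactors = FALSE),
      r_squared = s$r.squared)
  }
  pooled <- tidy_fit(stats::lm(emf11 ~ multidiv))
  per_climate <- lapply(levels(climate), function(lv) {
    sel <- climate == lv
    tidy_fit(stats::lm(emf11[sel] ~ multidiv[sel]))
  })
  names(per_climate) <- levels(climate)
  interaction <- tidy_fit(stats::lm(emf11 ~ multidiv * climate))
  structure(list(pooled = pooled, per_climate = per_climate,
                 interaction = interaction),
            class = "biodiv_emf_fits")
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' Pearson correlation and two-sided test p-value for every pair of
#' columns. Zero-variance columns are flagged and their pairs skipped
#' (`NA`).
#'
#' @param variables data.frame or matrix of per-plot columns (>= 3 rows)
#' @return list with symmetric matrices `r` and `p`, and
#'   `skipped` (names of zero-variance columns).
#' @export
correlation_matrix <- function(variables) {
  x <- as.data.frame(variables)
  if (nrow(x) < 3L) stop("need >= 3 observations", call. = FALSE)
  nm <- names(x)
  const <- nm[vapply(x, function(v) stats::var(v) == 0, logical(1))]
  k <- length(nm)
  r <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  p <- r
  diag(r) <- 1
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (nm[i] %in% const || nm[j] %in% const) next
      ct <- stats::cor.test(x[[i]], x[[j]])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(r = r, p = p, skipped = const)
}

#' Significance stars
#'
#' @param p p-value(s)
#' @return `"***"` below 0.001, `"**"` below 0.01, `"*"` below 0.05,
#'   `""` otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}
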