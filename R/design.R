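#' Generate a split-plot experimental design
#'
#' Lays out the two-factor split-plot design of the field experiment:
#' climate (ambient vs. future) is applied to whole mainplots, and each
#' mainplot contains every land-use type (EM, EP, IM, OF, CF) exactly once
#' as subplots. With the default 10 mainplots this yields 50 plots, i.e.
#' 5 replicates per climate x land-use cell.
#'
#' Climate levels are assigned to mainplots half/half at random, and the
#' order of land-use types within each mainplot is randomized, both under
#' `seed`, so the same seed reproduces the same table bit for bit.
#'
#' @param n_mainplots even number of mainplots (>= 2)
#' @param seed integer seed controlling the randomization
#' @return data.frame of class `plot_design` with columns `plot_id`,
#'   `mainplot_id`, `climate`, `lut`, `management`, `cover`, one row per
#'   plot.
#' @export
#' @examples
#' d <- generate_design(10, seed = 1)
#' table(d$climate, d$lut)  # 5 in every cell
generate_design <- function(n_mainplots = 10, seed = 1) {
  if (!is.numeric(n_mainplots) || length(n_mainplots) != 1L ||
      n_mainplots < 2 || n_mainplots %% 2 != 0) {
    stop("invalid design: n_mainplots must be an even number >= 2",
         call. = FALSE)
  }
  n_mainplots <- as.integer(n_mainplots)
  luts <- lut_levels()
  rows <- with_seed(seed, {
    climates <- sample(rep(c("ambient", "future"), each = n_mainplots / 2L))
    do.call(rbind, lapply(seq_len(n_mainplots), function(mp) {
      data.frame(
        mainplot_id = sprintf("MP%02d", mp),
        climate = climates[mp],
        lut = sample(luts),
        stringsAsFactors = FALSE
      )
    }))
  })
  rows$plot_id <- sprintf("%s_%s", rows$mainplot_id, rows$lut)
  rows$management <- lut_management(rows$lut)
  rows$cover <- lut_cover(rows$lut)
  out <- rows[, c("plot_id", "mainplot_id", "climate", "lut",
                  "management", "cover")]
  out$climate <- factor(out$climate, levels = c("ambient", "future"))
  out$lut <- factor(out$lut, levels = luts)
  class(out) <- c("plot_design", "data.frame")
  out
}

#' Validate a split-plot design table
#'
#' Checks the structural invariants: every mainplot holds each land-use
#' type exactly once, climate is constant within mainplots, and the design
#' is complete and balanced.
#'
#' @param design a `plot_design` data.frame (or compatible data.frame with
#'   the same columns)
#' @return `design`, invisibly; errors on violation.
#' @export
validate_design <- function(design) {
  need <- c("plot_id", "mainplot_id", "climate", "lut")
  miss <- setdiff(need, names(design))
  if (length(miss)) {
    stop("design lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab <- table(design$mainplot_id, design$lut)
  if (!all(tab == 1L)) {
    stop("invalid design: every mainplot must contain each land-use type ",
         "exactly once", call. = FALSE)
  }
  ncl <- tapply(as.character(design$climate), design$mainplot_id,
                function(x) length(unique(x)))
  if (any(ncl != 1L)) {
    stop("invalid design: climate must be constant within a mainplot",
         call. = FALSE)
  }
  cl_per_mp <- tapply(as.character(design$climate), design$mainplot_id,
                      `[`, 1L)
  if (length(unique(table(cl_per_mp))) != 1L ||
      length(unique(cl_per_mp)) != 2L) {
    stop("invalid design: mainplots must split half/half across the two ",
         "climates", call. = FALSE)
  }
  invisible(design)
}

# run an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed) %% .Machine$integer.max)
  }
  expr
}
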