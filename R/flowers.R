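#' Classify a pixel into a flower color class
#'
#' Applies the fixed RGB threshold rules, in order, with strict
#' inequalities; the first matching rule wins:
#'
#' * red: R > 200, G < 100, B < 100
#' * orange: R > 200, G > 100, 50 < B < 150
#' * blue: R < 100, G < 100, B > 200
#' * violet: R < 100, G < 100, B > 150, |R - B| < 50
#' * white: R > 200, G > 200, B > 200
#' * yellow: R > 200, G > 200, B < 100
#'
#' The violet rule is kept exactly as stated even though it is
#' unsatisfiable (R < 100 and B > 150 force |R - B| >= 52): it matches no
#' pixel. Boundary values (e.g. G = 100) match no class.
#'
#' @param r,g,b channel values in 0..255 (vectorized)
#' @return character vector of class labels, `NA` where no rule matches.
#' @export
#' @examples
#' classify_pixel(255, 50, 50)   # "red"
#' classify_pixel(90, 90, 160)   # NA: violet's |R - B| clause fails
classify_pixel <- function(r, g, b) {
  if (any(c(r, g, b) < 0) || any(c(r, g, b) > 255)) {
    stop("channel values must lie in 0..255", call. = FALSE)
  }
  out <- rep(NA_character_, length(r))
  rules <- list(
    red    = r > 200 & g < 100 & b < 100,
    orange = r > 200 & g > 100 & b > 50 & b < 150,
    blue   = r < 100 & g < 100 & b > 200,
    violet = r < 100 & g < 100 & b > 150 & abs(r - b) < 50,
    white  = r > 200 & g > 200 & b > 200,
    yellow = r > 200 & g > 200 & b < 100
  )
  for (cls in names(rules)) {
    hit <- is.na(out) & rules[[cls]]
    out[hit] <- cls
  }
  out
}

#' Flower color classes
#' @return the six class labels in rule order.
#' @export
flower_classes <- function() {
  c("red", "orange", "blue", "violet", "white", "yellow")
}

#' Count flower-color pixels in an image
#'
#' Iterates the threshold rules of [classify_pixel()] over every pixel and
#' reports per-class counts and the overall flower-pixel percentage.
#' Masked pixels (the manual blackout step used to remove non-flower
#' artifacts such as field equipment) are set to black before counting, so
#' they can never match a rule, but they remain in the denominator: the
#' percentage always divides by the full pixel count of the image.
#'
#' The optional `white_noise_correction` subtracts a constant percentage
#' from the white-class share (background glare on vegetation can be
#' misread as white flowers); it is off by default because downstream
#' min-max normalization absorbs a constant offset.
#'
#' @param image a `height x width x 3` (or `x 4`, alpha ignored) array
#'   with values in 0..255, or in \[0,1\] as returned by [png::readPNG()]
#' @param mask optional logical matrix (`height x width`); `TRUE` marks
#'   blacked-out pixels
#' @param white_noise_correction percentage points to subtract from the
#'   white share (default 0)
#' @return list of class `color_counts` with elements `counts` (named
#'   integer per class), `total_pixels`, `flower_fraction` (in \[0,1\])
#'   and `percent`.
#' @export
#' @examples
#' img <- generate_plot_image(100, 100, c(red = 0.07), seed = 1)
#' flower_fraction(img)$percent  # 7
flower_fraction <- function(image, mask = NULL,
                            white_noise_correction = 0) {
  img <- as_rgb255(image)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), c(h, w))) {
      stop("mask must be a logical matrix with the image's dimensions",
           call. = FALSE)
    }
    for (k in 1:3) {
      plane <- img[, , k]
      plane[mask] <- 0
      img[, , k] <- plane
    }
  }
  lab <- classify_pixel(as.vector(img[, , 1]), as.vector(img[, , 2]),
                        as.vector(img[, , 3]))
  counts <- vapply(flower_classes(),
                   function(cls) sum(lab == cls, na.rm = TRUE), integer(1))
  total <- h * w
  pct <- sum(counts) / total * 100
  if (white_noise_correction > 0) {
    white_pct <- max(counts[["white"]] / total * 100 -
                       white_noise_correction, 0)
    pct <- sum(counts[setdiff(names(counts), "white")]) / total * 100 +
      white_pct
  }
  structure(list(counts = counts, total_pixels = total,
                 flower_fraction = pct / 100, percent = pct),
            class = "color_counts")
}

#' Tabulate flower abundance for a set of image files
#'
#' Reads each PNG (or JPEG, if the jpeg package is available) image,
#' applies [flower_fraction()] and returns one row per file.
#'
#' @param paths image file paths
#' @param masks optional list of logical masks, one per file (or `NULL`)
#' @return data.frame with the filename, per-class counts and the flower
#'   percentage.
#' @export
flower_abundance_table <- function(paths, masks = NULL) {
  rows <- lapply(seq_along(paths), function(i) {
    img <- read_plot_image(paths[i])
    fc <- flower_fraction(img, mask = if (!is.null(masks)) masks[[i]])
    cbind(data.frame(file = basename(paths[i])),
          as.data.frame(as.list(fc$counts)),
          data.frame(total_pixels = fc$total_pixels,
                     percent = fc$percent))
  })
  do.call(rbind, rows)
}

#' Read / write plot images
#'
#' Thin wrappers over [png::readPNG()] / [png::writePNG()] (and
#' `jpeg::readJPEG()` for .jpg/.jpeg input) that keep the package's 0..255
#' integer convention.
#'
#' @param path image file path (.png, .jpg or .jpeg)
#' @return `read_plot_image` returns a `height x width x 3` array in
#'   0..255; `write_plot_image` returns `path` invisibly.
#' @export
read_plot_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE)) {
      stop("reading JPEG requires the jpeg package", call. = FALSE)
    }
    jpeg::readJPEG(path)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  as_rgb255(raw)
}

#' @rdname read_plot_image
#' @param image array in 0..255 (integers) or \[0,1\]
#' @export
write_plot_image <- function(image, path) {
  img <- as_rgb255(image)
  png::writePNG(img / 255, path)
  invisible(path)
}

# coerce an image array (RGB or RGBA, 0..255 or [0,1]) to h x w x 3 in
# 0..255
as_rgb255 <- function(image) {
  if (is.matrix(image)) {   # greyscale
    image <- array(rep(image, 3), dim = c(dim(image), 3L))
  }
  if (length(dim(image)) != 3L || !dim(image)[3] %in% c(3L, 4L)) {
    stop("image must be a height x width x 3 (or 4) array", call. = FALSE)
  }
  img <- unclass(image)[, , 1:3, drop = FALSE]
  if (max(img) <= 1 && min(img) >= 0) img <- img * 255
  if (any(img < 0) || any(img > 255)) {
    stop("channel values must lie in 0..255", call. = FALSE)
  }
  round(img)
}
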