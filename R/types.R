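#' Construct a grayscale image
#'
#' A `gray_image` is a numeric matrix (rows x cols) carrying its bit depth
#' and optional pixel spacing. Depths: `"8"` (integers in 0..255), `"16"`
#' (integers in 0..65535) and `"unit"` (doubles in \[0, 1\], the network's
#' input scale).
#'
#' @param pixels numeric matrix, rows x cols.
#' @param bit_depth one of `"8"`, `"16"`, `"unit"`.
#' @param spacing_mm optional pixel spacing in mm/pixel (length 1 or 2).
#' @return a `gray_image`.
#' @export
gray_image <- function(pixels, bit_depth = c("16", "8", "unit"),
                       spacing_mm = NULL) {
  bit_depth <- match.arg(bit_depth)
  if (!is.matrix(pixels) || nrow(pixels) < 1 || ncol(pixels) < 1)
    stop("pixels must be a non-empty matrix")
  rng <- range(pixels)
  lim <- switch(bit_depth, "8" = c(0, 255), "16" = c(0, 65535),
                unit = c(0, 1))
  if (rng[1] < lim[1] - 1e-9 || rng[2] > lim[2] + 1e-9)
    stop(sprintf("pixel values [%g, %g] outside the %s-depth range",
                 rng[1], rng[2], bit_depth))
  structure(pixels, bit_depth = bit_depth, spacing_mm = spacing_mm,
            class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, depth %s, range [%g, %g]>\n",
              nrow(x), ncol(x), attr(x, "bit_depth"),
              min(x), max(x)))
  invisible(x)
}

img_depth <- function(image) {
  d <- attr(image, "bit_depth")
  if (is.null(d)) {
    # bare matrices: infer conservatively from the value range
    m <- max(image)
    d <- if (m <= 1) "unit" else if (m <= 255) "8" else "16"
  }
  d
}

#' Construct a label map
#'
#' Integer matrix with values in `{1, 2, 3, 4}`: 1 background, 2 RV blood
#' pool, 3 LV myocardium, 4 LV blood pool.
#'
#' @param labels integer matrix.
#' @param n_classes number of classes (default 4).
#' @return a `label_map`.
#' @export
label_map <- function(labels, n_classes = 4L) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  v <- as.integer(labels)
  if (anyNA(v) || any(v < 1L) || any(v > n_classes))
    stop(sprintf("label values must lie in {1..%d}", n_classes))
  structure(matrix(v, nrow(labels), ncol(labels)),
            class = c("label_map", "matrix", "array"))
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map %d x %d, values {%s}>\n", nrow(x), ncol(x),
              paste(sort(unique(as.integer(x))), collapse = ",")))
  invisible(x)
}

check_same_shape <- function(a, b, what = "image and label") {
  if (nrow(a) != nrow(b) || ncol(a) != ncol(b))
    stop(sprintf("%s shapes differ: %dx%d vs %dx%d", what,
                 nrow(a), ncol(a), nrow(b), ncol(b)))
  invisible(TRUE)
}

#' Class labels used throughout the package
#'
#' @return named integer vector mapping structure names to label values.
#' @export
heart_classes <- function() {
  c(background = 1L, rv = 2L, myocardium = 3L, lv = 4L)
}
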