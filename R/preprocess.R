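#' Preprocessing configuration
#'
#' @param rows,cols target grid (default 160 x 128, the network input).
#' @param clahe_clip CLAHE clip limit as a fraction of the tile pixel count
#'   per histogram bin, in (0, 1]; default 0.01.
#' @param clahe_tiles tile grid as (tiles along rows, tiles along cols).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(rows = 160L, cols = 128L,
                              clahe_clip = 0.01, clahe_tiles = c(8L, 8L)) {
  stopifnot(rows >= 8, cols >= 8, clahe_clip > 0, clahe_clip <= 1,
            length(clahe_tiles) == 2, all(clahe_tiles >= 1))
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 clahe_clip = clahe_clip,
                 clahe_tiles = as.integer(clahe_tiles)),
            class = "preprocess_config")
}

# Interpolation weight matrix for one axis: D x S, each row holding the two
# bilinear weights of the half-pixel-centered source coordinate
# s = (d + 0.5) * S / D - 0.5, clamped to the valid range (no cropping, no
# padding: border pixels are extended).
bilinear_axis_weights <- function(S, D) {
  s <- (seq_len(D) - 0.5) * S / D - 0.5
  s <- pmin(pmax(s, 0), S - 1)
  lo <- pmin(floor(s), S - 2)
  if (S == 1) lo <- rep(0, D)
  frac <- s - lo
  Wm <- matrix(0, D, S)
  idx0 <- cbind(seq_len(D), lo + 1)
  Wm[idx0] <- Wm[idx0] + (1 - frac)
  idx1 <- cbind(seq_len(D), pmin(lo + 2, S))
  Wm[idx1] <- Wm[idx1] + frac
  Wm
}

#' Bilinear image resize
#'
#' Resizes to exactly `rows x cols` by separable bilinear interpolation with
#' half-pixel-centered coordinates; the full field of view is retained (no
#' cropping or padding).
#'
#' @param image a [gray_image()] or numeric matrix.
#' @param rows,cols target size.
#' @return resized image of the same bit depth (values continuous).
#' @export
resize_bilinear <- function(image, rows, cols) {
  if (rows < 1 || cols < 1) stop("target size must be positive")
  x <- unclass(image)
  attributes(x) <- attributes(x)["dim"]
  Rm <- bilinear_axis_weights(nrow(x), rows)
  Cm <- bilinear_axis_weights(ncol(x), cols)
  y <- Rm %*% x %*% t(Cm)
  if (inherits(image, "gray_image"))
    gray_image(y, bit_depth = img_depth(image),
               spacing_mm = attr(image, "spacing_mm"))
  else y
}

#' Nearest-neighbor label resize
#'
#' Output values are always a subset of the input's value set.
#'
#' @param label a [label_map()].
#' @param rows,cols target size.
#' @return resized [label_map()].
#' @export
resize_label <- function(label, rows, cols) {
  if (rows < 1 || cols < 1) stop("target size must be positive")
  nn_idx <- function(S, D) pmin(pmax(floor((seq_len(D) - 0.5) * S / D) + 1, 1), S)
  x <- matrix(as.integer(label), nrow(label), ncol(label))
  label_map(x[nn_idx(nrow(x), rows), nn_idx(ncol(x), cols), drop = FALSE])
}

#' Min-max normalization of a 16-bit image to 8-bit
#'
#' Per-image scaling of `[min, max]` onto `[0, 255]` with rounding; a
#' constant image maps to all zeros.
#'
#' @param image 16-bit [gray_image()] (continuous values allowed, e.g.
#'   after resizing).
#' @return 8-bit [gray_image()].
#' @export
normalize_to_8bit <- function(image) {
  x <- unclass(image)
  attributes(x) <- attributes(x)["dim"]
  rg <- range(x)
  y <- if (rg[2] > rg[1]) round((x - rg[1]) / (rg[2] - rg[1]) * 255)
       else matrix(0, nrow(x), ncol(x))
  gray_image(y, bit_depth = "8", spacing_mm = attr(image, "spacing_mm"))
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise clipped-histogram equalization with bilinear blending between
#' tile mappings (Zuiderveld's algorithm, via EBImage). The configured clip
#' fraction `f` is mapped to a clip limit of `f * bins` times the average
#' histogram height (256 bins), so the default 0.01 corresponds to the
#' customary limit.
#'
#' @param image 8-bit [gray_image()].
#' @param config a [preprocess_config()].
#' @return 8-bit [gray_image()].
#' @export
clahe <- function(image, config = preprocess_config()) {
  x <- unclass(image)
  attributes(x) <- attributes(x)["dim"]
  if (img_depth(image) != "8") stop("clahe expects an 8-bit image")
  tiles <- config$clahe_tiles
  if (tiles[1] > nrow(x) || tiles[2] > ncol(x))
    stop("CLAHE tile grid larger than the image")
  bins <- 256L
  y <- EBImage::clahe(x / 255, nx = tiles[1], ny = tiles[2], bins = bins,
                      limit = config$clahe_clip * bins)
  y <- pmin(pmax(round(y * 255), 0), 255)
  gray_image(matrix(y, nrow(x), ncol(x)), bit_depth = "8",
             spacing_mm = attr(image, "spacing_mm"))
}

#' Full preprocessing pipeline
#'
#' Resize to the target grid, normalize 16-bit input to 8-bit, apply CLAHE,
#' then scale to unit floats for the network:
#' resize -> (min-max to 8-bit if 16-bit) -> CLAHE -> /255.
#' Already-8-bit input skips the normalization stage (values are rounded
#' back to the 8-bit grid after the resize).
#'
#' @param image raw 8- or 16-bit [gray_image()].
#' @param config a [preprocess_config()].
#' @return unit-float [gray_image()] of the target shape, values in
#'   \[0, 1\].
#' @export
preprocess_pipeline <- function(image, config = preprocess_config()) {
  depth <- img_depth(image)
  if (!depth %in% c("8", "16"))
    stop("preprocess_pipeline expects raw 8- or 16-bit input")
  x <- resize_bilinear(image, config$rows, config$cols)
  x8 <- if (depth == "16") normalize_to_8bit(x)
        else gray_image(pmin(pmax(round(unclass(x)), 0), 255)[, , drop = FALSE],
                        bit_depth = "8", spacing_mm = attr(image, "spacing_mm"))
  y <- clahe(x8, config)
  gray_image(unclass(y) / 255, bit_depth = "unit",
             spacing_mm = attr(image, "spacing_mm"))
}
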