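#' Read a grayscale image from PNG or NIfTI
#'
#' PNG files (8- or 16-bit grayscale) are read whole; NIfTI volumes are read
#' as a single 2-D plane selected by `slice` (third dimension) and, for 4-D
#' cine files, `frame` (fourth dimension). The network is strictly 2-D, so
#' NIfTI orientation metadata beyond pixel spacing is ignored.
#'
#' @param path file path (`.png`, `.nii`, `.nii.gz`).
#' @param slice 1-based slice index for NIfTI input.
#' @param frame 1-based frame index for 4-D NIfTI input.
#' @return a [gray_image()].
#' @export
read_image <- function(path, slice = 1L, frame = 1L) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    x <- png::readPNG(path, info = TRUE)
    info <- attr(x, "info")
    if (length(dim(x)) == 3L) x <- x[, , 1L] # tolerate gray+alpha
    depth <- if (!is.null(info$bit.depth) && info$bit.depth == 16L) "16" else "8"
    scale <- if (depth == "16") 65535 else 255
    gray_image(round(unclass(x) * scale), bit_depth = depth)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    vol <- RNifti::readNifti(path)
    d <- dim(vol)
    pix <- RNifti::pixdim(vol)
    if (length(d) >= 3L && (slice < 1L || slice > d[3]))
      stop("slice index out of range: ", slice)
    if (length(d) >= 4L && (frame < 1L || frame > d[4]))
      stop("frame index out of range: ", frame)
    sl <- if (length(d) == 2L) vol[, ]
    else if (length(d) == 3L) vol[, , slice]
    else vol[, , slice, frame]
    hdr <- RNifti::niftiHeader(vol)
    depth <- if (hdr$datatype %in% c(2L, 256L)) "8" else "16"
    lim <- if (depth == "8") 255 else 65535
    gray_image(pmin(pmax(round(sl), 0), lim), bit_depth = depth,
               spacing_mm = if (length(pix) >= 2) pix[1:2] else NULL)
  } else {
    stop("unsupported image format: ", path)
  }
}

#' Write a grayscale image to PNG
#'
#' 8-bit images go through [png::writePNG()]; 16-bit images are written with
#' the package's own 16-bit grayscale PNG encoder. Unit-scale images are
#' stored as 16-bit. Round trips through [read_image()] are bit-exact.
#'
#' @param image a [gray_image()].
#' @param path output path ending in `.png`.
#' @export
write_image <- function(image, path) {
  depth <- img_depth(image)
  px <- unclass(image)
  attributes(px) <- attributes(px)["dim"]
  if (depth == "8") {
    png::writePNG(px / 255, path)
  } else {
    if (depth == "unit") px <- round(px * 65535)
    write_png16(px, path)
  }
  invisible(path)
}

#' Read a label map
#'
#' Two on-disk encodings are supported: `"internal"` stores the package's
#' native values `{1..4}` directly; `"acdc"` stores `{0..3}` (0 background,
#' 1 RV, 2 myocardium, 3 LV) and is remapped by +1 on ingest. NIfTI label
#' volumes are supported with the same `slice`/`frame` selection as
#' [read_image()].
#'
#' @param path file path.
#' @param encoding `"internal"` or `"acdc"`.
#' @param slice,frame plane selection for NIfTI input.
#' @return a [label_map()].
#' @export
read_label <- function(path, encoding = c("internal", "acdc"),
                       slice = 1L, frame = 1L) {
  encoding <- match.arg(encoding)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    x <- png::readPNG(path)
    if (length(dim(x)) == 3L) x <- x[, , 1L]
    v <- round(unclass(x) * 255)
  } else {
    v <- unclass(read_image(path, slice = slice, frame = frame))
    attributes(v) <- attributes(v)["dim"]
  }
  allowed <- if (encoding == "acdc") 0:3 else 1:4
  bad <- setdiff(unique(as.integer(v)), allowed)
  if (length(bad) > 0)
    stop(sprintf("label values {%s} outside the '%s' encoding {%s}",
                 paste(bad, collapse = ","), encoding,
                 paste(range(allowed), collapse = "..")))
  if (encoding == "acdc") v <- v + 1L
  label_map(matrix(as.integer(v), nrow(v), ncol(v)))
}

#' Write a label map as an 8-bit PNG storing the internal values
#'
#' @param label a [label_map()].
#' @param path output path.
#' @export
write_label <- function(label, path) {
  px <- matrix(as.integer(label), nrow(label), ncol(label))
  png::writePNG(px / 255, path)
  invisible(path)
}

#' Write a color overlay of a segmentation on a grayscale image
#'
#' Follows the standard display convention: LV blood pool red, LV
#' myocardium green, RV blood pool blue; background shows the grayscale
#' image.
#'
#' @param image a [gray_image()] (any depth).
#' @param label a [label_map()] of the same shape.
#' @param path output PNG path.
#' @export
write_overlay <- function(image, label, path) {
  check_same_shape(image, label)
  depth <- img_depth(image)
  g <- unclass(image) / switch(depth, "8" = 255, "16" = 65535, unit = 1)
  attributes(g) <- attributes(g)["dim"]
  r <- g; gr <- g; b <- g
  lv <- label == 4L; my <- label == 3L; rv <- label == 2L
  r[lv] <- 1; gr[lv] <- 0; b[lv] <- 0
  r[my] <- 0; gr[my] <- 1; b[my] <- 0
  r[rv] <- 0; gr[rv] <- 0; b[rv] <- 1
  png::writePNG(array(c(r, gr, b), dim = c(nrow(g), ncol(g), 3L)), path)
  invisible(path)
}

#' Read and write dataset manifests
#'
#' A manifest is a tab-separated table with columns `image`, `label`,
#' `split` (train/valid/test), `slice` (apex/mid/base) and `phase` (ED/ES).
#' Paths are stored relative to the manifest file and resolved on read.
#'
#' @param path manifest file path.
#' @return a `data.frame` with absolute paths.
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("image", "label", "split", "slice", "phase")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (!all(m$split %in% c("train", "valid", "test")))
    stop("invalid split tags in manifest")
  base <- dirname(normalizePath(path))
  abs <- function(p) ifelse(p == "" | grepl("^/", p), p, file.path(base, p))
  m$image <- abs(m$image)
  m$label <- abs(m$label)
  missing <- c(m$image, m$label[m$label != ""])
  missing <- missing[!file.exists(missing)]
  if (length(missing) > 0)
    stop("manifest references missing files, e.g. ", missing[1])
  m
}

#' @rdname read_manifest
#' @param manifest data.frame as above.
#' @export
write_manifest <- function(manifest, path) {
  m <- manifest
  base <- dirname(normalizePath(path, mustWork = FALSE))
  rel <- function(p) ifelse(startsWith(p, paste0(base, "/")),
                            substring(p, nchar(base) + 2L), p)
  m$image <- rel(m$image)
  m$label <- rel(m$label)
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
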