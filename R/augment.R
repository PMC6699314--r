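#' Augmentation configuration
#'
#' Ranges for the random on-the-fly augmentation applied to training
#' minibatches: affine geometry (scaling, rotation, shearing, translation),
#' Gaussian noise, Gaussian blur and elastic deformation. Each transform is
#' included independently with probability `prob`; its parameter is then
#' drawn uniformly from the given range. Defaults are conservative for
#' 160 x 128 cardiac frames.
#'
#' @param scale_range multiplicative scale factor range.
#' @param rotation_range rotation range, degrees.
#' @param shear_range shear range, degrees.
#' @param translation_range per-axis translation range, pixels.
#' @param noise_range additive Gaussian noise sigma range (unit intensity
#'   scale).
#' @param blur_range Gaussian blur sigma range, pixels.
#' @param elastic_alpha_range elastic displacement amplitude range, pixels.
#' @param elastic_sigma_range elastic smoothness (Gaussian sigma) range,
#'   pixels.
#' @param prob per-transform application probability.
#' @return an `augment_config` list.
#' @export
augment_config <- function(scale_range = c(0.9, 1.1),
                           rotation_range = c(-15, 15),
                           shear_range = c(-8, 8),
                           translation_range = c(-10, 10),
                           noise_range = c(0, 0.03),
                           blur_range = c(0, 1.5),
                           elastic_alpha_range = c(0, 10),
                           elastic_sigma_range = c(4, 8),
                           prob = 0.5) {
  rngs <- list(scale_range, rotation_range, shear_range, translation_range,
               noise_range, blur_range, elastic_alpha_range,
               elastic_sigma_range)
  ok <- vapply(rngs, function(r) length(r) == 2 && all(is.finite(r)) &&
                 r[1] <= r[2], logical(1))
  if (!all(ok)) stop("augmentation ranges must be finite intervals")
  stopifnot(prob >= 0, prob <= 1)
  structure(list(scale_range = scale_range, rotation_range = rotation_range,
                 shear_range = shear_range,
                 translation_range = translation_range,
                 noise_range = noise_range, blur_range = blur_range,
                 elastic_alpha_range = elastic_alpha_range,
                 elastic_sigma_range = elastic_sigma_range, prob = prob),
            class = "augment_config")
}

#' Disable all augmentation
#' @return an `augment_config` whose sampled transforms are always identity.
#' @export
augment_off <- function() augment_config(prob = 0)

#' Sample a concrete transform for one minibatch item
#'
#' All draws come from the supplied stream; the returned spec fully
#' determines the transform (including the seeds of its stochastic parts),
#' so applying it is deterministic and serializable.
#'
#' @param config an [augment_config()].
#' @param rng stream from [rng_new()].
#' @return a `transform_spec`.
#' @export
sample_transform <- function(config, rng) {
  stopifnot(inherits(config, "augment_config"))
  p <- config$prob
  on_flags <- rng_runif(rng, 7) < p
  draw <- function(on, range, id) if (on) rng_runif(rng, 1, range[1], range[2]) else id
  spec <- list(
    scale = draw(on_flags[1], config$scale_range, 1),
    rotation = draw(on_flags[2], config$rotation_range, 0),
    shear = draw(on_flags[3], config$shear_range, 0),
    translation = if (on_flags[4])
      c(rng_runif(rng, 1, config$translation_range[1], config$translation_range[2]),
        rng_runif(rng, 1, config$translation_range[1], config$translation_range[2]))
      else c(0, 0),
    noise_sd = draw(on_flags[5], config$noise_range, 0),
    blur_sd = draw(on_flags[6], config$blur_range, 0),
    elastic_alpha = draw(on_flags[7], config$elastic_alpha_range, 0),
    elastic_sigma = if (on_flags[7])
      rng_runif(rng, 1, config$elastic_sigma_range[1],
                config$elastic_sigma_range[2]) else 4,
    elastic_seed = floor(rng_runif(rng, 1, 0, 2^31 - 1)),
    noise_seed = floor(rng_runif(rng, 1, 0, 2^31 - 1))
  )
  structure(spec, class = "transform_spec")
}

#' Identity transform spec
#' @return a `transform_spec` that leaves image and label untouched.
#' @export
identity_transform <- function() {
  structure(list(scale = 1, rotation = 0, shear = 0, translation = c(0, 0),
                 noise_sd = 0, blur_sd = 0, elastic_alpha = 0,
                 elastic_sigma = 4, elastic_seed = 0, noise_seed = 0),
            class = "transform_spec")
}

is_identity_geometry <- function(spec) {
  spec$scale == 1 && spec$rotation == 0 && spec$shear == 0 &&
    all(spec$translation == 0)
}

# Bilinear resampling at continuous source coordinates (1-based);
# out-of-bounds positions take `fill`.
resample_bilinear <- function(x, sr, sc, fill = 0) {
  H <- nrow(x); W <- ncol(x)
  valid <- sr >= 1 & sr <= H & sc >= 1 & sc <= W
  r0 <- pmin(pmax(floor(sr), 1), H - 1)
  c0 <- pmin(pmax(floor(sc), 1), W - 1)
  fr <- pmin(pmax(sr - r0, 0), 1)
  fc <- pmin(pmax(sc - c0, 0), 1)
  i00 <- r0 + H * (c0 - 1)
  v <- (1 - fr) * (1 - fc) * x[i00] + fr * (1 - fc) * x[i00 + 1] +
    (1 - fr) * fc * x[i00 + H] + fr * fc * x[i00 + H + 1]
  v[!valid] <- fill
  matrix(v, H, W)
}

# Nearest-neighbor resampling; out-of-bounds positions take `fill`.
resample_nearest <- function(x, sr, sc, fill = 1L) {
  H <- nrow(x); W <- ncol(x)
  rn <- round(sr); cn <- round(sc)
  valid <- rn >= 1 & rn <= H & cn >= 1 & cn <= W
  rn <- pmin(pmax(rn, 1), H); cn <- pmin(pmax(cn, 1), W)
  v <- x[rn + H * (cn - 1)]
  v[!valid] <- fill
  matrix(v, H, W)
}

# Separable Gaussian blur with replicate borders, as two banded matrix
# products.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  band <- function(n) {
    r <- max(1L, ceiling(3 * sigma))
    k <- exp(-(-r:r)^2 / (2 * sigma^2))
    k <- k / sum(k)
    B <- matrix(0, n, n)
    i <- seq_len(n)
    for (j in -r:r) {
      idx <- pmin(pmax(i + j, 1L), n)
      B[cbind(i, idx)] <- B[cbind(i, idx)] + k[j + r + 1]
    }
    B
  }
  band(nrow(x)) %*% x %*% t(band(ncol(x)))
}

#' Random elastic deformation of a paired image and label
#'
#' The displacement field is zero-mean Gaussian noise smoothed with a
#' Gaussian of width `sigma`, rescaled to unit standard deviation and
#' multiplied by `alpha` (so displacements have standard deviation `alpha`
#' pixels). The image is resampled bilinearly, the label with
#' nearest-neighbor, through the same field. `alpha = 0` is the identity.
#'
#' @param image unit-float image matrix.
#' @param label paired [label_map()].
#' @param alpha displacement amplitude, pixels (>= 0).
#' @param sigma field smoothness, pixels (> 0).
#' @param rng stream from [rng_new()].
#' @return `list(image, label)`.
#' @export
elastic_deform <- function(image, label, alpha, sigma, rng) {
  stopifnot(alpha >= 0, sigma > 0)
  check_same_shape(image, label)
  if (alpha == 0) return(list(image = image, label = label))
  H <- nrow(image); W <- ncol(image)
  smooth_field <- function() {
    f <- gaussian_blur(matrix(rng_rnorm(rng, H * W), H, W), sigma)
    f / max(stats::sd(f), 1e-12) * alpha
  }
  dr <- smooth_field()
  dc <- smooth_field()
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  img <- resample_bilinear(unclass(image), rr + dr, cc + dc, fill = 0)
  lab <- resample_nearest(matrix(as.integer(label), H, W), rr + dr, cc + dc,
                          fill = 1L)
  list(image = img, label = label_map(lab))
}

#' Apply a sampled transform to a paired image and label
#'
#' The affine map (scale, rotation, shear about the image center, then
#' translation) and the elastic field are applied to both grids with the
#' same geometry: bilinear interpolation for the image (out-of-bounds fill
#' 0) and nearest-neighbor for the label (fill 1, background). Noise and
#' blur act on the image only. Output shapes equal input shapes and the
#' image is clipped back to \[0, 1\].
#'
#' @param image unit-float image matrix.
#' @param label paired [label_map()].
#' @param spec a `transform_spec` from [sample_transform()].
#' @return `list(image, label)`.
#' @export
apply_transform <- function(image, label, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  check_same_shape(image, label)
  img <- unclass(image)
  attributes(img) <- attributes(img)["dim"]
  lab <- matrix(as.integer(label), nrow(label), ncol(label))
  H <- nrow(img); W <- ncol(img)

  if (!is_identity_geometry(spec)) {
    th <- spec$rotation * pi / 180
    sh <- tan(spec$shear * pi / 180)
    A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) %*%
      matrix(c(1, 0, sh, 1), 2, 2) * spec$scale
    Ainv <- solve(A)
    ctr <- c((H + 1) / 2, (W + 1) / 2)
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    pr <- rr - ctr[1] - spec$translation[1]
    pc <- cc - ctr[2] - spec$translation[2]
    sr <- Ainv[1, 1] * pr + Ainv[1, 2] * pc + ctr[1]
    sc <- Ainv[2, 1] * pr + Ainv[2, 2] * pc + ctr[2]
    img <- resample_bilinear(img, sr, sc, fill = 0)
    lab <- resample_nearest(lab, sr, sc, fill = 1L)
  }
  if (spec$elastic_alpha > 0) {
    ed <- elastic_deform(img, label_map(lab), spec$elastic_alpha,
                         spec$elastic_sigma, rng_new(spec$elastic_seed))
    img <- ed$image
    lab <- matrix(as.integer(ed$label), H, W)
  }
  if (spec$blur_sd > 0) img <- gaussian_blur(img, spec$blur_sd)
  if (spec$noise_sd > 0) {
    img <- img + matrix(rng_rnorm(rng_new(spec$noise_seed), H * W,
                                  0, spec$noise_sd), H, W)
  }
  if (spec$blur_sd > 0 || spec$noise_sd > 0 || !is_identity_geometry(spec) ||
      spec$elastic_alpha > 0)
    img <- pmin(pmax(img, 0), 1)
  list(image = img, label = label_map(lab))
}

#' Augment a minibatch in memory
#'
#' Draws an independent `transform_spec` per item and applies it; inputs
#' are untouched, outputs are fresh grids, and nothing is written to disk.
#'
#' @param images list of unit-float image matrices.
#' @param labels list of paired [label_map()]s.
#' @param config an [augment_config()].
#' @param rng stream from [rng_new()].
#' @return `list(images, labels, specs)`.
#' @export
augment_minibatch <- function(images, labels, config, rng) {
  if (length(images) != length(labels))
    stop("image and label batches differ in length")
  specs <- lapply(seq_along(images), function(i) sample_transform(config, rng))
  out <- Map(function(im, lb, sp) apply_transform(im, lb, sp),
             images, labels, specs)
  list(images = lapply(out, `[[`, "image"),
       labels = lapply(out, `[[`, "label"),
       specs = specs)
}
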