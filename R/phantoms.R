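#' Configuration for the synthetic short-axis cardiac phantom
#'
#' The phantom emulates the appearance of an SSFP bright-blood short-axis
#' frame: a circular LV blood pool (label 4) inside a concentric myocardial
#' annulus (label 3) with an RV crescent (label 2) attached to its left, on
#' a darker background (label 1), with intensity ordering
#' blood > myocardium > background, a smooth additive bias field and
#' additive Gaussian noise. Slice modes mimic the anatomy along the
#' long axis: `apex` shrinks the ventricle and omits the RV entirely (so a
#' class is genuinely absent from the label map, exercising the
#' absent-class loss path), `base` adds a bright unlabeled distractor blob
#' (a stand-in for out-of-plane vessels such as the pulmonary artery).
#'
#' @param rows,cols grid size in pixels (default 160 x 128).
#' @param lv_radius end-diastolic LV blood-pool radius, pixels.
#' @param myo_thickness myocardial wall thickness, pixels.
#' @param rv_offset distance from the LV center to the RV disk center,
#'   pixels (the crescent forms to the left of the annulus).
#' @param rv_thickness maximal crescent thickness, pixels.
#' @param contraction end-systolic LV radius as a fraction of the
#'   end-diastolic radius, in (0, 1].
#' @param intensities named triplet `(blood, myo, background)` on the
#'   16-bit scale; must be strictly decreasing in that order.
#' @param noise_sigma standard deviation of additive Gaussian noise,
#'   16-bit units.
#' @param bias_amplitude peak amplitude of the smooth additive bias field,
#'   16-bit units.
#' @param slice_mode `"mid"`, `"apex"` or `"base"`.
#' @param shift length-2 respiratory translation of the heart
#'   (rows, cols), pixels.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(rows = 160L, cols = 128L,
                           lv_radius = 18, myo_thickness = 7,
                           rv_offset = 20, rv_thickness = 10,
                           contraction = 0.8,
                           intensities = c(blood = 42000, myo = 20000,
                                           background = 7000),
                           noise_sigma = 1800, bias_amplitude = 5000,
                           slice_mode = c("mid", "apex", "base"),
                           shift = c(0, 0)) {
  slice_mode <- match.arg(slice_mode)
  stopifnot(rows >= 16, cols >= 16, lv_radius > 0, myo_thickness > 0,
            rv_offset > 0, rv_thickness > 0,
            contraction > 0, contraction <= 1,
            noise_sigma >= 0, bias_amplitude >= 0, length(shift) == 2)
  if (!(intensities[1] > intensities[2] && intensities[2] > intensities[3]))
    stop("intensities must be ordered blood > myocardium > background")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 lv_radius = lv_radius, myo_thickness = myo_thickness,
                 rv_offset = rv_offset, rv_thickness = rv_thickness,
                 contraction = contraction, intensities = intensities,
                 noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
                 slice_mode = slice_mode, shift = shift),
            class = "phantom_config")
}

#' Generate one synthetic short-axis phantom frame
#'
#' @param config a [phantom_config()].
#' @param seed integer seed; identical `(config, seed)` give bit-identical
#'   output.
#' @param phase `"ED"` or `"ES"`; ES applies the configured contraction to
#'   the LV blood pool (the outer myocardial boundary is kept, so the wall
#'   thickens, as in systole).
#' @return `list(image, label)`: a 16-bit [gray_image()] and its paired
#'   [label_map()].
#' @export
generate_phantom <- function(config, seed = 1L, phase = c("ED", "ES")) {
  phase <- match.arg(phase)
  stopifnot(inherits(config, "phantom_config"))
  rng <- rng_new(seed)
  H <- config$rows; W <- config$cols
  scale <- if (config$slice_mode == "apex") 0.55 else 1
  lv_r <- config$lv_radius * scale
  myo_t <- config$myo_thickness * scale
  if (phase == "ES") lv_r <- lv_r * config$contraction
  outer_r <- config$lv_radius * scale + myo_t # ED outer boundary retained
  cr <- H / 2 + config$shift[1]
  cc <- W / 2 + config$shift[2]
  if (cr - outer_r < 1 || cr + outer_r > H || cc - outer_r < 1)
    stop("phantom geometry does not fit the grid")

  rr <- matrix(seq_len(H), H, W)
  cm <- matrix(seq_len(W), H, W, byrow = TRUE)
  d_lv <- sqrt((rr - cr)^2 + (cm - cc)^2)
  lab <- matrix(1L, H, W)
  lab[d_lv <= outer_r] <- 3L
  lab[d_lv <= lv_r] <- 4L

  if (config$slice_mode != "apex") {
    rv_t <- config$rv_thickness *
      (if (phase == "ES") config$contraction else 1)
    rv_r <- outer_r + rv_t - config$rv_offset
    if (rv_r <= 0) stop("RV geometry degenerate: offset too large")
    d_rv <- sqrt((rr - cr)^2 + (cm - (cc - config$rv_offset))^2)
    lab[d_rv <= rv_r & d_lv > outer_r] <- 2L
    if (cc - config$rv_offset - rv_r < 1)
      stop("phantom geometry does not fit the grid")
  }

  ints <- config$intensities
  img <- matrix(ints[["background"]], H, W)
  img[lab == 3L] <- ints[["myo"]]
  img[lab %in% c(2L, 4L)] <- ints[["blood"]]

  if (config$slice_mode == "base") {
    # unlabeled bright distractor outside the heart (stays background)
    bc <- c(cr - 0.28 * H, cc + 0.30 * W)
    d_b <- sqrt((rr - bc[1])^2 + (cm - bc[2])^2)
    img[d_b <= 8 & lab == 1L] <- ints[["blood"]]
  }

  if (config$bias_amplitude > 0) {
    u <- (rr - H / 2) / H
    v <- (cm - W / 2) / W
    b <- rng_runif(rng, 5, -1, 1)
    field <- b[1] * u + b[2] * v + b[3] * u * v + b[4] * u^2 + b[5] * v^2
    field <- field / max(abs(field), 1e-12) * config$bias_amplitude
    img <- img + field
  }
  if (config$noise_sigma > 0)
    img <- img + matrix(rng_rnorm(rng, H * W, 0, config$noise_sigma), H, W)
  img <- round(pmin(pmax(img, 0), 65535))

  list(image = gray_image(img, bit_depth = "16"), label = label_map(lab))
}

#' Generate a phantom dataset on disk with a manifest
#'
#' Writes `n` 16-bit image PNGs with paired label PNGs, mixing cardiac
#' phases (ED/ES), slice modes and respiratory shifts, and a tab-separated
#' manifest partitioning them into train/valid/test splits. Fully
#' reproducible for a fixed seed. When `slice_mode = "mix"` and `n >= 4`
#' at least one apex frame (absent RV class) is always present.
#'
#' @param n number of frames.
#' @param config base [phantom_config()]; per-frame mode/phase/shift vary.
#' @param seed integer seed.
#' @param out_dir output directory (created if needed).
#' @param splits length-3 fractions (train, valid, test) summing to 1.
#' @param slice_mode `"mix"` (default) or a fixed mode for every frame.
#' @param max_shift respiratory shifts drawn uniformly from
#'   `[-max_shift, max_shift]` per axis.
#' @return the manifest `data.frame` (invisibly also written to
#'   `out_dir/manifest.tsv`).
#' @export
generate_dataset <- function(n, config = phantom_config(), seed = 1L,
                             out_dir, splits = c(0.8, 0.1, 0.1),
                             slice_mode = c("mix", "mid", "apex", "base"),
                             max_shift = 6) {
  slice_mode <- match.arg(slice_mode)
  stopifnot(n >= 1, length(splits) == 3, abs(sum(splits) - 1) < 1e-9)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rng <- rng_new(seed)

  modes <- if (slice_mode == "mix") {
    m <- rng_sample(rng, c("apex", "mid", "base"), n, replace = TRUE)
    if (n >= 4 && !any(m == "apex")) m[1] <- "apex"
    m
  } else rep(slice_mode, n)
  phases <- rng_sample(rng, c("ED", "ES"), n, replace = TRUE)
  shifts_r <- round(rng_runif(rng, n, -max_shift, max_shift))
  shifts_c <- round(rng_runif(rng, n, -max_shift, max_shift))
  frame_seeds <- floor(rng_runif(rng, n, 0, 2^31 - 1))

  counts <- diff(c(0, round(cumsum(splits) * n)))
  split_tags <- rep(c("train", "valid", "test"), counts)
  split_tags <- split_tags[rng_sample(rng, seq_len(n))]

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config
    cfg$slice_mode <- modes[i]
    cfg$shift <- c(shifts_r[i], shifts_c[i])
    ph <- generate_phantom(cfg, seed = frame_seeds[i], phase = phases[i])
    img_path <- file.path(out_dir, sprintf("img_%04d.png", i))
    lab_path <- file.path(out_dir, sprintf("lab_%04d.png", i))
    write_image(ph$image, img_path)
    write_label(ph$label, lab_path)
    rows[[i]] <- data.frame(image = img_path, label = lab_path,
                            split = split_tags[i], slice = modes[i],
                            phase = phases[i], stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  manifest
}
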