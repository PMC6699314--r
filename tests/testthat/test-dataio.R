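test_that("PNG round trips are bit-exact at both bit depths", {
  set.seed(10)
  px8 <- matrix(sample(0:255, 40 * 30, replace = TRUE), 40, 30)
  f8 <- withr::local_tempfile(fileext = ".png")
  write_image(gray_image(px8, "8"), f8)
  back8 <- read_image(f8)
  expect_equal(attr(back8, "bit_depth"), "8")
  expect_identical(matrix(as.numeric(back8), 40, 30), px8 * 1.0)

  px16 <- matrix(sample(0:65535, 40 * 30, replace = TRUE), 40, 30)
  px16[1] <- 0; px16[2] <- 65535
  f16 <- withr::local_tempfile(fileext = ".png")
  write_image(gray_image(px16, "16"), f16)
  back16 <- read_image(f16)
  expect_equal(attr(back16, "bit_depth"), "16")
  expect_identical(matrix(as.numeric(back16), 40, 30), px16 * 1.0)
})

test_that("16-bit PNG values pass through unscaled (max 4095 stays 4095)", {
  px <- matrix(0, 8, 8)
  px[3, 3] <- 4095
  f <- withr::local_tempfile(fileext = ".png")
  write_image(gray_image(px, "16"), f)
  back <- read_image(f)
  expect_equal(attr(back, "bit_depth"), "16")
  expect_equal(max(back), 4095)
})

test_that("NIfTI slice extraction honors shape and bounds", {
  vol <- array(as.integer(round(runif(16 * 12 * 3, 0, 1000))), c(16, 12, 3))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), f)
  sl <- read_image(f, slice = 3)
  expect_equal(dim(sl), c(16L, 12L))
  expect_equal(matrix(as.numeric(sl), 16, 12), vol[, , 3] * 1.0)
  expect_error(read_image(f, slice = 4), "out of range")
})

test_that("label encodings: internal passthrough, acdc remap, bad values rejected", {
  lab <- matrix(c(1L, 3L, 4L, 1L), 2, 2)
  f <- withr::local_tempfile(fileext = ".png")
  write_label(label_map(lab), f)
  expect_identical(matrix(as.integer(read_label(f, "internal")), 2, 2), lab)

  # acdc-style file storing {0..3}
  acdc <- matrix(0:3, 2, 2)
  fa <- withr::local_tempfile(fileext = ".png")
  png::writePNG(acdc / 255, fa)
  remapped <- read_label(fa, "acdc")
  expect_identical(matrix(as.integer(remapped), 2, 2), acdc + 1L)
  # remap is a bijection {0..3} -> {1..4}
  expect_setequal(as.integer(remapped), 1:4)

  bad <- matrix(c(1, 5, 1, 1), 2, 2)
  fb <- withr::local_tempfile(fileext = ".png")
  png::writePNG(bad / 255, fb)
  expect_error(read_label(fb, "internal"), "encoding")
  expect_error(read_label(fa, "internal"), "encoding") # 0 invalid internally
})

test_that("overlay colors follow the LV-red / myo-green / RV-blue convention", {
  img <- gray_image(matrix(128, 4, 4), "8")
  lab <- matrix(1L, 4, 4)
  lab[1, 1] <- 4L; lab[2, 2] <- 3L; lab[3, 3] <- 2L
  f <- withr::local_tempfile(fileext = ".png")
  write_overlay(img, label_map(lab), f)
  rgb <- png::readPNG(f)
  expect_equal(rgb[1, 1, ], c(1, 0, 0))            # LV red
  expect_equal(rgb[2, 2, ], c(0, 1, 0))            # myocardium green
  expect_equal(rgb[3, 3, ], c(0, 0, 1))            # RV blue
  expect_equal(rgb[4, 4, ], rep(128 / 255, 3), tolerance = 1e-2) # background gray
  # all-background overlay is the grayscale image replicated to RGB
  f2 <- withr::local_tempfile(fileext = ".png")
  write_overlay(img, label_map(matrix(1L, 4, 4)), f2)
  rgb2 <- png::readPNG(f2)
  expect_true(all(abs(rgb2 - 128 / 255) < 1e-2))
  expect_error(write_overlay(img, label_map(matrix(1L, 3, 3)), f2), "shapes")
})

test_that("manifests round trip with relative paths and validate splits", {
  d <- withr::local_tempdir()
  ph <- generate_phantom(phantom_config(), seed = 1)
  write_image(ph$image, file.path(d, "img.png"))
  write_label(ph$label, file.path(d, "lab.png"))
  m <- data.frame(image = file.path(d, "img.png"),
                  label = file.path(d, "lab.png"),
                  split = "train", slice = "mid", phase = "ED")
  write_manifest(m, file.path(d, "manifest.tsv"))
  back <- read_manifest(file.path(d, "manifest.tsv"))
  expect_true(file.exists(back$image[1]))
  m$split <- "bogus"
  write_manifest(m, file.path(d, "m2.tsv"))
  expect_error(read_manifest(file.path(d, "m2.tsv")), "split")
})
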