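# Image I/O, luma/chroma handling and the synthetic phantom generator.

test_that("load/save round trip is bounded by 8-bit quantization", {
  dir <- withr::local_tempdir()
  for (seed in 1:10) {
    x <- seeded_image(24, 31, seed = seed)
    p <- file.path(dir, sprintf("img%02d.png", seed))
    save_image(p, x)
    expect_lte(max(abs(load_image(p) - x)), 1 / 255)
  }
  # extremes map exactly
  p <- file.path(dir, "ones.png")
  save_image(p, matrix(1, 16, 16))
  expect_equal(load_image(p), matrix(1, 16, 16))
  save_image(p, matrix(0, 16, 16))
  expect_equal(load_image(p), matrix(0, 16, 16))
  # constant mid-gray loads uniform
  save_image(p, matrix(0.5, 16, 16))
  expect_equal(length(unique(c(load_image(p)))), 1L)
})

test_that("TIFF and color files round trip; equal-channel RGB collapses to gray", {
  dir <- withr::local_tempdir()
  x <- seeded_image(20, 20, seed = 3)
  rgb_gray <- array(rep(x, 3), c(20, 20, 3))
  p <- file.path(dir, "gray3.tif")
  save_image(p, rgb_gray)
  got <- load_image(p)
  expect_true(is.matrix(got))            # channel-equality collapse
  expect_lte(max(abs(got - x)), 1 / 255)

  col <- withr::with_seed(4, array(stats::runif(20 * 20 * 3), c(20, 20, 3)))
  p2 <- file.path(dir, "color.png")
  save_image(p2, col)
  got2 <- load_image(p2)
  expect_equal(dim(got2), c(20L, 20L, 3L))
  expect_lte(max(abs(got2 - col)), 1 / 255)
})

test_that("unreadable paths raise errors", {
  expect_error(load_image(file.path(tempdir(), "no_such_file.png")))
  expect_error(save_image(file.path(tempdir(), "no_such_dir_xyz", "a.png"),
                          matrix(0.5, 16, 16)))
})

test_that("luma/chroma split is the fixed BT.601 transform and inverts exactly", {
  # hand-evaluated luma of the primaries
  red <- array(0, c(4, 4, 3)); red[, , 1] <- 1
  blue <- array(0, c(4, 4, 3)); blue[, , 3] <- 1
  expect_equal(split_luma_chroma(red)$luma[1, 1], 0.299)
  expect_equal(split_luma_chroma(blue)$luma[1, 1], 0.114)
  expect_false(isTRUE(all.equal(split_luma_chroma(red)$chroma,
                                split_luma_chroma(blue)$chroma)))

  # gray RGB -> luma v, neutral chroma
  v <- seeded_image(8, 8, seed = 5)
  gray <- array(rep(v, 3), c(8, 8, 3))
  lc <- split_luma_chroma(gray)
  expect_equal(lc$luma, v, tolerance = 1e-12)
  expect_lte(max(abs(lc$chroma)), 1e-12)
  expect_equal(merge_luma_chroma(v, lc$chroma * 0), gray, tolerance = 1e-12)

  # round trip on random color images
  for (seed in 1:5) {
    col <- withr::with_seed(seed, array(stats::runif(12 * 12 * 3), c(12, 12, 3)))
    lc <- split_luma_chroma(col)
    expect_lte(max(abs(merge_luma_chroma(lc$luma, lc$chroma) - col)), 1e-6)
  }
})

test_that("merge_luma_chroma clips out-of-gamut values into [0, 1]", {
  chroma <- array(0.6, c(8, 8, 2))           # strong chroma, mid luma
  out <- merge_luma_chroma(matrix(0.5, 8, 8), chroma)
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)
  expect_error(merge_luma_chroma(matrix(0.5, 8, 9), chroma))
})

test_that("phantom pairs are seeded, co-registered and structured as specified", {
  spec <- phantom_spec(seed = 11)
  p1 <- generate_phantom_pair(spec)
  p2 <- generate_phantom_pair(spec)
  expect_identical(p1$mri, p2$mri)           # bitwise reproducibility
  expect_identical(p1$pet, p2$pet)
  expect_identical(p1$labels, p2$labels)     # shared anatomy by construction

  expect_true(all(p1$mri >= 0 & p1$mri <= 1))
  expect_true(all(p1$pet >= 0 & p1$pet <= 1))
  expect_equal(dim(p1$pet), c(128L, 128L, 3L))

  # different seeds differ
  expect_false(identical(generate_phantom_pair(phantom_spec(seed = 12))$mri,
                         p1$mri))
  expect_error(phantom_spec(shape = c(8L, 8L)))
})

test_that("noise/texture-free phantom is piecewise constant with boundary-dominated gradient", {
  spec <- phantom_spec(noise_sigma = 0, texture_amp = 0, seed = 2)
  p <- generate_phantom_pair(spec)
  # interior pixels away from any label change have zero forward differences
  lab <- p$labels
  n <- nrow(lab); m <- ncol(lab)
  same <- lab[1:(n - 1), 1:(m - 1)] == lab[1:(n - 1), 2:m] &
    lab[1:(n - 1), 1:(m - 1)] == lab[2:n, 1:(m - 1)]
  dx <- p$mri[1:(n - 1), 2:m] - p$mri[1:(n - 1), 1:(m - 1)]
  dy <- p$mri[2:n, 1:(m - 1)] - p$mri[1:(n - 1), 1:(m - 1)]
  g <- sqrt((dx^2 + dy^2) / 2)
  expect_equal(max(g[same]), 0)
  expect_gt(mean(g[!same]), 0.01)            # boundaries carry the gradient

  # hotspot_amp = 0 leaves the smooth anatomical base as PET luma
  spec0 <- phantom_spec(hotspot_amp = 0, noise_sigma = 0, seed = 2)
  spec1 <- phantom_spec(hotspot_amp = 0.5, noise_sigma = 0, seed = 2)
  p0 <- generate_phantom_pair(spec0)
  p1 <- generate_phantom_pair(spec1)
  expect_false(isTRUE(all.equal(p0$pet_luma, p1$pet_luma)))
  expect_gte(max(p1$pet_luma - p0$pet_luma) + 1e-8, 0)  # hotspot only adds
})

test_that("NIfTI slice extraction rescales to [0, 1]", {
  skip_if_not_installed("RNifti")
  vol <- withr::with_seed(8, array(stats::rnorm(16 * 16 * 4, 50, 20),
                                   c(16, 16, 4)))
  path <- file.path(withr::local_tempdir(), "vol.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  sl <- load_nifti_slice(path, 2)
  expect_equal(dim(sl), c(16L, 16L))
  expect_equal(range(sl), c(0, 1))
  expect_error(load_nifti_slice(path, 9))
})
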