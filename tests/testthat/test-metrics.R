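# The eight fusion-quality measures.

test_that("entropy matches closed forms", {
  expect_equal(entropy_image(matrix(0.42, 16, 16)), 0)
  # each 8-bit level exactly 256 times -> exactly 8 bits
  x <- matrix(rep(0:255, each = 256) / 255, 256, 256)
  expect_equal(entropy_image(x), 8)
  # two equal-mass levels -> 1 bit
  y <- matrix(rep(c(0, 1), each = 128), 16, 16)
  expect_equal(entropy_image(y), 1)
})

test_that("fusion PSNR matches closed forms and is symmetric in the sources", {
  a <- seeded_image(32, seed = 1)
  expect_identical(psnr_fusion(a, a, a), Inf)
  # uniform one-gray-level error against both sources
  f <- matrix(128 / 255, 32, 32)
  a1 <- matrix(127 / 255, 32, 32); b1 <- matrix(129 / 255, 32, 32)
  expect_equal(psnr_fusion(f, a1, b1), 10 * log10(255^2), tolerance = 1e-9)
  b <- seeded_image(32, seed = 2); g <- seeded_image(32, seed = 3)
  expect_equal(psnr_fusion(g, a, b), psnr_fusion(g, b, a))
  expect_error(psnr_fusion(g, a, matrix(0, 32, 31)))
})

test_that("fusion MI matches entropy identities", {
  a <- seeded_image(64, seed = 5)
  expect_equal(mi_fusion(a, a, a), 2 * entropy_image(a), tolerance = 1e-9)
  # a constant source contributes zero information
  f <- seeded_image(64, seed = 6)
  expect_equal(mi_fusion(f, f, matrix(0.5, 64, 64)), entropy_image(f),
               tolerance = 1e-9)
  # an independent source contributes only the chance-agreement bias of the
  # 256x256-bin histogram estimator (Miller-Madow: (K-1)(L-1)/(2N ln 2))
  f2 <- seeded_image(256, seed = 7)
  b2 <- seeded_image(256, seed = 8)
  # first-order bias; higher-order terms matter at one sample per bin, so
  # agreement is asserted to 25%
  chance_bias <- 255^2 / (2 * length(f2) * log(2))
  extra <- mi_fusion(f2, f2, b2) - entropy_image(f2)
  expect_lte(abs(extra - chance_bias), 0.25 * chance_bias)
})

test_that("average gradient matches the ramp closed form", {
  expect_equal(average_gradient(matrix(0.8, 16, 16)), 0)
  # horizontal ramp with slope 2 gray-levels/pixel
  ramp <- matrix(rep(seq_len(32) * 2 / 255, each = 32), 32, 32)
  expect_equal(average_gradient(ramp), 2 / sqrt(2), tolerance = 1e-9)
  x <- seeded_image(24, seed = 9)
  expect_equal(average_gradient(x), average_gradient(t(x)))
})

test_that("fusion SSIM attains 1 only on perfect agreement and is symmetric", {
  a <- seeded_image(32, seed = 10)
  expect_equal(ssim_fusion(a, a, a), 1, tolerance = 1e-12)
  expect_lt(ssim_fusion(1 - a, a, a), 1)
  b <- seeded_image(32, seed = 11); f <- (a + b) / 2
  expect_equal(ssim_fusion(f, a, b), ssim_fusion(f, b, a))
})

test_that("edge triple sums to one and tracks transfer quality", {
  # unity identity across random and phantom triples
  for (seed in 1:10) {
    f <- seeded_image(32, seed = seed)
    a <- seeded_image(32, seed = seed + 20)
    b <- seeded_image(32, seed = seed + 40)
    expect_equal(sum(edge_metrics(f, a, b)), 1, tolerance = 1e-6)
  }
  for (seed in 1:10) {
    p <- generate_phantom_pair(phantom_spec(shape = c(64L, 64L), seed = seed))
    f <- mean_fuse(p$mri, p$pet_luma)
    expect_equal(sum(edge_metrics(f, p$mri, p$pet_luma)), 1, tolerance = 1e-6)
  }

  # perfect transfer: fused equals both sources
  s <- generate_phantom_pair(phantom_spec(seed = 3))$mri
  em <- edge_metrics(s, s, s)
  expect_gte(em["qabf"], 0.95)
  expect_lte(em["nabf"], 0.02)

  # no transfer: constant fused image
  a <- generate_phantom_pair(phantom_spec(seed = 4))$mri
  b <- generate_phantom_pair(phantom_spec(seed = 5))$mri
  em0 <- edge_metrics(matrix(0.5, 128, 128), a, b)
  expect_lte(em0["qabf"], 0.1)
})

test_that("metric_report collects all eight measures consistently", {
  p <- generate_phantom_pair(phantom_spec(shape = c(64L, 64L), seed = 6))
  f <- mean_fuse(p$mri, p$pet_luma)
  m <- metric_report(f, p$mri, p$pet_luma)
  expect_named(unclass(m), c("en", "psnr", "mi", "ag", "qabf", "ssim",
                             "labf", "nabf"))
  expect_equal(m$qabf + m$labf + m$nabf, 1, tolerance = 1e-6)
  expect_gte(m$en, 0); expect_lte(m$en, 8)
  expect_gte(m$mi, 0); expect_gte(m$psnr, 0)
  df <- as.data.frame(m)
  expect_equal(df$ssim, m$ssim)
})
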