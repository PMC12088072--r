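# Windowed normalized filters and the rolling-guidance cascade.

# separable window min/max used by the convexity check
window_extremum_range <- function(x, r) {
  list(mn = fusemd:::window_extremum(x, r, "min"),
       mx = fusemd:::window_extremum(x, r, "max"))
}

test_that("constant images are fixed points and degenerate limits reduce correctly", {
  const <- matrix(0.37, 16, 16)
  p <- rgf_params(sigma_s = 2, sigma_r = 0.1, n_iter = 3)
  expect_equal(gaussian_smooth(const, p), const, tolerance = 1e-12)
  expect_equal(joint_bilateral(const, const, p), const, tolerance = 1e-12)
  expect_equal(rolling_guidance(const, p), const, tolerance = 1e-12)

  x <- seeded_image(16, seed = 1)
  # constant guide makes the range factor 1 -> plain Gaussian smoothing
  expect_equal(joint_bilateral(x, matrix(1, 16, 16), p),
               gaussian_smooth(x, p), tolerance = 1e-12)
  # enormous sigma_r likewise
  p_wide <- rgf_params(sigma_s = 2, sigma_r = 1e6)
  expect_lte(max(abs(joint_bilateral(x, x, p_wide) - gaussian_smooth(x, p_wide))),
             1e-9)
  # zero joint-bilateral stages: rolling guidance is the Gaussian pre-filter
  p0 <- rgf_params(sigma_s = 2, sigma_r = 0.1, n_iter = 0)
  expect_equal(rolling_guidance(x, p0), gaussian_smooth(x, p0))
})

test_that("vectorized filters match the per-pixel double-loop oracle", {
  for (seed in 1:5) {
    x <- seeded_image(16, seed = seed)
    g <- seeded_image(16, seed = seed + 100)
    p <- rgf_params(sigma_s = 1.5, sigma_r = 0.15, radius = 4)
    expect_lte(max(abs(gaussian_smooth(x, p) -
                         bf_oracle(x, NULL, 1.5, radius = 4))), 1e-10)
    expect_lte(max(abs(joint_bilateral(x, g, p) -
                         bf_oracle(x, g, 1.5, 0.15, radius = 4))), 1e-10)
  }
})

test_that("impulse response center equals the normalized window weight", {
  x <- matrix(0, 9, 9); x[5, 5] <- 1
  p <- rgf_params(sigma_s = 1, radius = 2)
  w <- outer(-2:2, -2:2, function(a, b) exp(-(a^2 + b^2) / 2))
  expect_equal(gaussian_smooth(x, p)[5, 5], w[3, 3] / sum(w), tolerance = 1e-12)
})

test_that("joint bilateral filtering respects a two-level step", {
  x <- step_image(8)
  p <- rgf_params(sigma_s = 2, sigma_r = 0.05)
  out <- joint_bilateral(x, x, p)
  expect_lte(max(abs(out - x)), 0.01)        # each side keeps its own level
})

test_that("every output pixel is a convex combination of input window values", {
  for (seed in 1:3) {
    x <- seeded_image(20, seed = seed)
    p <- rgf_params(sigma_s = 2, sigma_r = 0.1, n_iter = 2)
    for (out in list(gaussian_smooth(x, p), joint_bilateral(x, x, p),
                     rolling_guidance(x, p))) {
      lo <- window_extremum_range(x, p$radius)
      expect_true(all(out >= lo$mn - 1e-12 & out <= lo$mx + 1e-12))
    }
  }
})

test_that("rolling guidance removes fine texture while keeping large steps", {
  n <- 64
  step <- step_image(n, 0.1, 0.9)            # amplitude 0.8
  check <- 0.1 * outer((-1)^(1:n), (-1)^(1:n))
  x <- step + check
  out <- rolling_guidance(x, rgf_params(sigma_s = 3, sigma_r = 0.1, n_iter = 4))

  off_edge <- col(x) %in% c(5:27, 38:60)     # away from the step and borders
  amp_in <- pattern_amplitude(x, check, off_edge)
  amp_out <- pattern_amplitude(out, check, off_edge)
  expect_lte(abs(amp_out), 0.1 * abs(amp_in))          # texture suppressed

  step_in <- mean(x[, 38:60]) - mean(x[, 5:27])
  step_out <- mean(out[, 38:60]) - mean(out[, 5:27])
  expect_gte(step_out, 0.8 * step_in)                  # step retained

  # contraction toward edge-preserving smoothing: total variation of the
  # cascade output never exceeds the textured input's
  tv <- function(img) sum(abs(diff(img))) + sum(abs(t(diff(t(img)))))
  expect_lte(tv(out), tv(x))
})

test_that("non-finite input and size mismatches are rejected", {
  x <- matrix(1, 8, 8); x[2, 2] <- NA
  expect_error(gaussian_smooth(x, rgf_params()))
  expect_error(joint_bilateral(matrix(0, 8, 8), matrix(0, 8, 9), rgf_params()))
})
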