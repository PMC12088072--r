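# Shared fixtures and independent brute-force oracles.

seeded_image <- function(n, m = n, seed = 1) {
  withr::with_seed(seed, matrix(stats::runif(n * m), n, m))
}

# Product grating sin(2*pi*x/period) * sin(2*pi*y/period): a genuinely
# two-dimensional oscillation with strict point extrema (a 1-D grating has
# ridge lines of tied neighbours and no strict 2-D extrema).
product_grating <- function(n, period, amp = 1) {
  s <- sin(2 * pi * seq_len(n) / period)
  amp * outer(s, s)
}

# Vertical step of the given amplitude at the image midline.
step_image <- function(n, lo = 0, hi = 1) {
  cbind(matrix(lo, n, n %/% 2), matrix(hi, n, n - n %/% 2))
}

# Literal per-pixel double-loop evaluation of the windowed normalized
# filter: Gaussian weights when `guide` is NULL, joint-bilateral weights
# computed on `guide` otherwise.  Reflect boundary via index folding.
bf_oracle <- function(image, guide = NULL, sigma_s, sigma_r = NULL, radius) {
  n <- nrow(image); m <- ncol(image)
  refl <- function(i, len) {
    j <- ((i - 1) %% (2 * len)) + 1
    if (j > len) 2 * len - j + 1 else j
  }
  out <- matrix(0, n, m)
  for (p in 1:n) for (q in 1:m) {
    num <- 0; den <- 0
    for (dr in -radius:radius) for (dc in -radius:radius) {
      r <- refl(p + dr, n); s <- refl(q + dc, m)
      w <- exp(-(dr^2 + dc^2) / (2 * sigma_s^2))
      if (!is.null(guide))
        w <- w * exp(-(guide[p, q] - guide[r, s])^2 / (2 * sigma_r^2))
      num <- num + image[r, s] * w
      den <- den + w
    }
    out[p, q] <- num / den
  }
  out
}

# Energy of the component of `img` proportional to `pattern` (projection).
pattern_amplitude <- function(img, pattern, mask = NULL) {
  if (!is.null(mask)) { img <- img[mask]; pattern <- pattern[mask] }
  sum(img * pattern) / sum(pattern * pattern)
}
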