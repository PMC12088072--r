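# Objective fusion-quality measures.  All metrics take intensities on the
# internal [0,1] scale and convert to the 8-bit convention internally:
# histogram-based measures (EN, MI) quantize to 256 levels, difference-based
# measures (PSNR, AG, SSIM) use the continuous value times 255.

quantize256 <- function(x) as.integer(round(clamp01(x) * 255))

#' Shannon entropy of an image
#'
#' Entropy in bits of the 256-bin intensity histogram (8-bit quantization);
#' empty bins contribute zero.
#'
#' @param image Numeric matrix on the \[0,1\] scale.
#' @return Entropy in bits, in \[0, 8\].
#' @export
entropy_image <- function(image) {
  assert_image(image)
  p <- tabulate(quantize256(image) + 1L, 256L) / length(image)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Fusion peak signal-to-noise ratio
#'
#' `10*log10(255^2 / MSEbar)` where `MSEbar` is the mean of the two
#' mean-squared errors between the fused image and each source, on the 8-bit
#' scale.  Returns `Inf` when the fused image equals both sources.
#'
#' @param f Fused image.
#' @param a,b Source images, same size as `f`.
#' @return PSNR in dB.
#' @export
psnr_fusion <- function(f, a, b) {
  assert_image(f); assert_image(a); assert_image(b)
  assert_same_size(f, a); assert_same_size(f, b)
  mse <- (mean((255 * (f - a))^2) + mean((255 * (f - b))^2)) / 2
  if (mse == 0) return(Inf)
  10 * log10(255^2 / mse)
}

# Mutual information between two quantized images, 256x256 joint histogram,
# log base 2.
mi_pair <- function(x, y) {
  qx <- quantize256(x); qy <- quantize256(y)
  joint <- matrix(tabulate(qx * 256L + qy + 1L, 65536L) / length(qx),
                  256L, 256L)               # joint[i, j] = p(y = i-1, x = j-1)
  py <- rowSums(joint); px <- colSums(joint)
  prod_marg <- py %o% px
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / prod_marg[nz]))
}

#' Fusion mutual information
#'
#' `MI(f, a) + MI(f, b)` in bits, each term computed from the 256 x 256
#' joint histogram of the 8-bit quantized images — the amount of source
#' information carried into the fused image.
#'
#' @inheritParams psnr_fusion
#' @return Mutual information in bits (non-negative).
#' @export
mi_fusion <- function(f, a, b) {
  assert_image(f); assert_image(a); assert_image(b)
  assert_same_size(f, a); assert_same_size(f, b)
  mi_pair(f, a) + mi_pair(f, b)
}

#' Average gradient of an image
#'
#' Mean over interior pixels of `sqrt((dx^2 + dy^2)/2)` with forward
#' differences, on the 8-bit intensity scale — a sharpness measure.
#'
#' @param image Numeric matrix with both sides >= 2.
#' @return Average gradient in gray-levels per pixel.
#' @export
average_gradient <- function(image) {
  assert_image(image, min_side = 2L)
  x <- 255 * image
  n <- nrow(x); m <- ncol(x)
  dx <- x[1:(n - 1L), 2:m, drop = FALSE] - x[1:(n - 1L), 1:(m - 1L), drop = FALSE]
  dy <- x[2:n, 1:(m - 1L), drop = FALSE] - x[1:(n - 1L), 1:(m - 1L), drop = FALSE]
  mean(sqrt((dx^2 + dy^2) / 2))
}

# Single-scale SSIM between two images on the 8-bit scale: 11x11 Gaussian
# window sigma 1.5, K1 = 0.01, K2 = 0.03, dynamic range 255.
ssim_pair <- function(x, y) {
  k <- gauss_kernel(1.5, 5L)
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  x <- 255 * x; y <- 255 * y
  mu_x <- convolve_sep(x, k); mu_y <- convolve_sep(y, k)
  sxx <- convolve_sep(x * x, k) - mu_x^2
  syy <- convolve_sep(y * y, k) - mu_y^2
  sxy <- convolve_sep(x * y, k) - mu_x * mu_y
  mean(((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
         ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2)))
}

#' Fusion structural similarity
#'
#' Mean of `SSIM(f, a)` and `SSIM(f, b)` with the standard single-scale SSIM
#' (11 x 11 Gaussian window, sigma 1.5, K1 = 0.01, K2 = 0.03, range 255).
#'
#' @inheritParams psnr_fusion
#' @return SSIM value, at most 1 (1 iff `f` equals both sources).
#' @export
ssim_fusion <- function(f, a, b) {
  assert_image(f, min_side = 11L); assert_image(a); assert_image(b)
  assert_same_size(f, a); assert_same_size(f, b)
  (ssim_pair(f, a) + ssim_pair(f, b)) / 2
}

# Sobel gradient strength and orientation.
sobel_grad <- function(x) {
  n <- nrow(x); m <- ncol(x)
  p <- pad_reflect(x, 1L)
  sh <- function(dr, dc) p[(2L + dr):(n + 1L + dr), (2L + dc):(m + 1L + dc), drop = FALSE]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  g <- sqrt(gx^2 + gy^2)
  alpha <- atan(ifelse(gx == 0, ifelse(gy == 0, 0, sign(gy) * Inf), gy / gx))
  list(g = g, alpha = alpha)
}

# Per-pixel edge-preservation of source s in fused f (Xydeas-Petrovic
# sigmoid model with the standard published constants).
edge_preservation <- function(src, fus) {
  gamma_g <- 0.9994; kappa_g <- -15; sigma_g <- 0.5
  gamma_a <- 0.9879; kappa_a <- -22; sigma_a <- 0.8
  gmin <- pmin(src$g, fus$g); gmax <- pmax(src$g, fus$g)
  grel <- ifelse(gmax == 0, 0, gmin / gmax)
  arel <- 1 - abs(src$alpha - fus$alpha) / (pi / 2)
  qg <- gamma_g / (1 + exp(kappa_g * (grel - sigma_g)))
  qa <- gamma_a / (1 + exp(kappa_a * (arel - sigma_a)))
  qg * qa
}

#' Edge-information triple QABF / LABF / NABF
#'
#' Xydeas-Petrovic edge-transfer analysis of a fusion result: Sobel gradient
#' strength and orientation are compared between each source and the fused
#' image through sigmoid preservation models, weighted by source edge
#' strength.  `qabf` is the preserved fraction of source edge information,
#' `labf` the fraction lost (under-represented in the fused image), and
#' `nabf` the artifact fraction attributed to pixels where the fused gradient
#' exceeds both sources.  The three partition the total edge information and
#' sum to unity.
#'
#' @inheritParams psnr_fusion
#' @return Named numeric vector `c(qabf, labf, nabf)` summing to 1.
#' @export
edge_metrics <- function(f, a, b) {
  assert_image(f); assert_image(a); assert_image(b)
  assert_same_size(f, a); assert_same_size(f, b)
  ga <- sobel_grad(a); gb <- sobel_grad(b); gf <- sobel_grad(f)
  qaf <- edge_preservation(ga, gf)
  qbf <- edge_preservation(gb, gf)
  wa <- ga$g; wb <- gb$g
  wtot <- sum(wa) + sum(wb)
  if (wtot == 0) return(c(qabf = 0, labf = 0, nabf = 0))
  artifact <- gf$g > pmax(ga$g, gb$g)
  qabf <- sum(qaf * wa + qbf * wb) / wtot
  loss <- (1 - qaf) * wa + (1 - qbf) * wb
  labf <- sum(loss[!artifact]) / wtot
  nabf <- sum(loss[artifact]) / wtot
  out <- c(qabf = qabf, labf = labf, nabf = nabf)
  out / sum(out)   # unity identity enforced exactly
}

#' Full fusion-quality report
#'
#' Computes all eight fusion metrics for a fused image `f` against its two
#' sources `a` and `b`.
#'
#' @inheritParams psnr_fusion
#' @return An object of class `metric_report`: named list with elements
#'   `en`, `psnr`, `mi`, `ag`, `qabf`, `ssim`, `labf`, `nabf`.
#' @export
#' @examples
#' a <- matrix(runif(64 * 64), 64, 64); b <- matrix(runif(64 * 64), 64, 64)
#' metric_report((a + b) / 2, a, b)
metric_report <- function(f, a, b) {
  em <- edge_metrics(f, a, b)
  structure(list(en = entropy_image(f), psnr = psnr_fusion(f, a, b),
                 mi = mi_fusion(f, a, b), ag = average_gradient(f),
                 qabf = unname(em["qabf"]), ssim = ssim_fusion(f, a, b),
                 labf = unname(em["labf"]), nabf = unname(em["nabf"])),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  v <- unlist(x)
  cat("Fusion quality metrics:\n")
  print(round(v, digits))
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}
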