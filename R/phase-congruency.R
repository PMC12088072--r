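#' Phase-congruency parameters
#'
#' Settings of the log-Gabor filter bank and noise compensation behind the
#' phase-congruency measure.
#'
#' @param n_scales Number of filter scales (>= 2).
#' @param n_orientations Number of filter orientations (>= 2).
#' @param min_wavelength Wavelength in pixels of the smallest-scale filter
#'   (>= 2).
#' @param scale_mult Multiplier between successive filter wavelengths.
#' @param sigma_on_f Ratio defining the log-Gabor radial bandwidth (the
#'   standard deviation of the Gaussian on the log-frequency axis divided by
#'   the filter centre frequency); 0.55 gives about two octaves.
#' @param noise_k Number of noise-amplitude standard deviations above the
#'   estimated noise energy used as the significance threshold.
#' @param cut_off,gain Parameters of the frequency-spread sigmoid weighting:
#'   locations where only a narrow range of filter scales responds (e.g.
#'   smooth ramps, far tails of a lone edge) are down-weighted, since phase
#'   agreement of a single component carries no information.
#' @param epsilon Small stabilizer preventing division by zero.
#' @return An object of class `pc_params`.
#' @export
pc_params <- function(n_scales = 4L, n_orientations = 6L, min_wavelength = 3,
                      scale_mult = 2.1, sigma_on_f = 0.55, noise_k = 2,
                      cut_off = 0.5, gain = 10, epsilon = 1e-4) {
  stopifnot(n_scales >= 2, n_orientations >= 2, min_wavelength >= 2)
  structure(list(n_scales = as.integer(n_scales),
                 n_orientations = as.integer(n_orientations),
                 min_wavelength = min_wavelength, scale_mult = scale_mult,
                 sigma_on_f = sigma_on_f, noise_k = noise_k,
                 cut_off = cut_off, gain = gain, epsilon = epsilon),
            class = "pc_params")
}

#' Phase congruency of an image
#'
#' Computes the per-pixel phase-congruency significance measure from a bank
#' of log-Gabor quadrature filters: at each orientation the local energy
#' (phase-aligned part of the filter responses, after subtracting an
#' estimated noise energy threshold) is normalized by the total response
#' amplitude over scales, then summed over orientations.  The result lies in
#' \[0,1\], is invariant to global intensity offsets (the filters have no DC
#' response) and peaks on edges and lines regardless of their contrast
#' polarity.
#'
#' Filtering is done in the frequency domain.  The image is extended to
#' twice its size by even-symmetric mirroring before the transform so that
#' the implicit periodic extension is continuous and the image borders do
#' not masquerade as edges; the result is cropped back to the input size.
#'
#' @param image Numeric matrix with both sides >= 16.
#' @param params A [pc_params()] object.
#' @return An object of class `pc_map`: list with `values` (matrix in
#'   \[0,1\]) and `params_used`.
#' @export
#' @examples
#' x <- cbind(matrix(0, 32, 16), matrix(1, 32, 16))
#' pc <- phase_congruency(x)
#' range(pc$values)
phase_congruency <- function(image, params = pc_params()) {
  assert_image(image, min_side = 16L)
  n0 <- nrow(image); m0 <- ncol(image)
  # even-symmetric (mirror) extension to 2n x 2m: the periodic tiling seen
  # by the FFT is then continuous, so image borders do not read as edges
  image <- image[c(1:n0, n0:1), c(1:m0, m0:1), drop = FALSE]
  n <- nrow(image); m <- ncol(image)
  ft <- stats::fft(image)

  # centred, ifftshifted normalized frequency grids
  fy <- c(0:(n / 2 - 1), -(n / 2):-1) / n
  fx <- c(0:(m / 2 - 1), -(m / 2):-1) / m
  radius <- sqrt(outer(fy^2, fx^2, `+`))
  radius[1, 1] <- 1                       # avoid log(0) at DC
  theta <- outer(fy, fx, function(y, x) atan2(-y, x))
  sintheta <- sin(theta); costheta <- cos(theta)

  # radial low-pass keeps the corner frequencies from aliasing
  lowpass <- 1 / (1 + (radius / 0.45)^30)

  log_gabor <- vector("list", params$n_scales)
  for (s in seq_len(params$n_scales)) {
    fo <- 1 / (params$min_wavelength * params$scale_mult^(s - 1))
    lg <- exp(-(log(radius / fo))^2 / (2 * log(params$sigma_on_f)^2)) * lowpass
    lg[1, 1] <- 0
    log_gabor[[s]] <- lg
  }

  dtheta_sigma <- pi / params$n_orientations / 1.3
  eps <- params$epsilon
  total_energy <- matrix(0, n, m)
  total_sum_an <- matrix(0, n, m)

  for (o in seq_len(params$n_orientations)) {
    angl <- (o - 1) * pi / params$n_orientations
    ds <- sintheta * cos(angl) - costheta * sin(angl)
    dc <- costheta * cos(angl) + sintheta * sin(angl)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * dtheta_sigma^2))

    sum_e <- matrix(0, n, m); sum_o <- matrix(0, n, m)
    sum_an <- matrix(0, n, m); max_an <- matrix(0, n, m)
    e_list <- vector("list", params$n_scales)
    o_list <- vector("list", params$n_scales)
    tau <- 0
    for (s in seq_len(params$n_scales)) {
      filt <- log_gabor[[s]] * spread
      resp <- stats::fft(ft * filt, inverse = TRUE) / length(ft)
      e <- Re(resp); od <- Im(resp)
      an <- sqrt(e^2 + od^2)
      sum_e <- sum_e + e; sum_o <- sum_o + od; sum_an <- sum_an + an
      max_an <- pmax(max_an, an)
      e_list[[s]] <- e; o_list[[s]] <- od
      if (s == 1L) tau <- stats::median(an) / sqrt(log(4))
    }

    energy_mag <- sqrt(sum_e^2 + sum_o^2)
    mean_e <- sum_e / (energy_mag + eps)
    mean_o <- sum_o / (energy_mag + eps)
    energy <- matrix(0, n, m)
    for (s in seq_len(params$n_scales))
      energy <- energy + e_list[[s]] * mean_e + o_list[[s]] * mean_o -
        abs(e_list[[s]] * mean_o - o_list[[s]] * mean_e)

    # Rayleigh noise model propagated through the scale sum
    total_tau <- tau * (1 - (1 / params$scale_mult)^params$n_scales) /
      (1 - 1 / params$scale_mult)
    noise_mean <- total_tau * sqrt(pi / 2)
    noise_sd <- total_tau * sqrt((4 - pi) / 2)
    t_thresh <- noise_mean + params$noise_k * noise_sd

    # frequency-spread weighting: fraction of the scale range responding
    width <- (sum_an / (max_an + eps) - 1) / (params$n_scales - 1)
    weight <- 1 / (1 + exp(params$gain * (params$cut_off - width)))

    total_energy <- total_energy + weight * pmax(energy - t_thresh, 0)
    total_sum_an <- total_sum_an + sum_an
  }

  pc <- total_energy / (total_sum_an + eps)
  pc <- clamp01(pc)[1:n0, 1:m0, drop = FALSE]
  structure(list(values = pc, params_used = params), class = "pc_map")
}

#' @export
print.pc_map <- function(x, ...) {
  cat(sprintf("Phase-congruency map %s, range [%.3f, %.3f]\n",
              paste(dim(x$values), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Fuse two corresponding IMFs by phase-congruency significance
#'
#' Each output pixel takes the value of whichever input has the larger
#' phase-congruency at that pixel; exact ties take the mean of the two
#' values.  The alternative `"soft"` rule blends the inputs with weights
#' proportional to their phase-congruency values.
#'
#' @param imf_a,imf_b Numeric matrices of equal size (corresponding IMFs of
#'   the two modalities).
#' @param params A [pc_params()] object.
#' @param rule `"select"` (default, hard maximum-significance selection) or
#'   `"soft"` (significance-weighted average).
#' @return The fused matrix.
#' @export
pc_fuse <- function(imf_a, imf_b, params = pc_params(),
                    rule = c("select", "soft")) {
  rule <- match.arg(rule)
  assert_image(imf_a); assert_image(imf_b)
  assert_same_size(imf_a, imf_b, "IMFs")
  pa <- phase_congruency(imf_a, params)$values
  pb <- phase_congruency(imf_b, params)$values
  if (rule == "select") {
    out <- (imf_a + imf_b) / 2
    out[pa > pb] <- imf_a[pa > pb]
    out[pb > pa] <- imf_b[pb > pa]
  } else {
    wa <- (pa + params$epsilon) / (pa + pb + 2 * params$epsilon)
    out <- wa * imf_a + (1 - wa) * imf_b
  }
  out
}
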