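#' Sifting parameters for bidimensional empirical mode decomposition
#'
#' @param max_sift_iters Cap on sifting iterations per IMF (>= 1).
#' @param sd_tol Cauchy-type stop threshold on the normalized squared change
#'   between successive sifting iterates,
#'   `SD = sum((h_k - h_{k-1})^2) / sum(h_{k-1}^2)`.
#' @param min_extrema Minimum total count of strict maxima plus strict minima
#'   required to sift; with fewer the band is treated as a residue already.
#'   The default 4 requires at least two extrema of each kind on average,
#'   the least support on which upper and lower envelopes are meaningful.
#' @param envelope_smooth_sigma Standard deviation (pixels) of the Gaussian
#'   used to smooth the nearest-extremum envelope surfaces; `NULL` (default)
#'   sizes it from the mean extrema spacing of the current iterate.
#' @return An object of class `sift_params`.
#' @export
sift_params <- function(max_sift_iters = 8L, sd_tol = 0.2, min_extrema = 4L,
                        envelope_smooth_sigma = NULL) {
  stopifnot(max_sift_iters >= 1, sd_tol > 0, min_extrema >= 1)
  structure(list(max_sift_iters = as.integer(max_sift_iters),
                 sd_tol = sd_tol, min_extrema = as.integer(min_extrema),
                 envelope_smooth_sigma = envelope_smooth_sigma),
            class = "sift_params")
}

#' Locate strict local extrema of an image
#'
#' A pixel is a maximum (minimum) iff it is strictly greater (smaller) than
#' every one of its existing 8-neighbours; border pixels compare against the
#' neighbours they have.  The two masks are disjoint by construction.
#'
#' @param image Numeric matrix.
#' @return A list with logical matrices `maxima` and `minima`.
#' @export
find_extrema <- function(image) {
  assert_image(image)
  n <- nrow(image); m <- ncol(image)
  lo <- matrix(-Inf, n + 2L, m + 2L); lo[2:(n + 1L), 2:(m + 1L)] <- image
  hi <- matrix(Inf, n + 2L, m + 2L); hi[2:(n + 1L), 2:(m + 1L)] <- image
  nb_max <- matrix(-Inf, n, m); nb_min <- matrix(Inf, n, m)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    rows <- (2L + dr):(n + 1L + dr); cols <- (2L + dc):(m + 1L + dc)
    nb_max <- pmax(nb_max, lo[rows, cols, drop = FALSE])
    nb_min <- pmin(nb_min, hi[rows, cols, drop = FALSE])
  }
  list(maxima = image > nb_max, minima = image < nb_min)
}

#' Envelope surface through masked sample points
#'
#' Builds a smooth surface supported only by the image values at the masked
#' sites: every pixel first takes the value of its nearest masked site
#' (nearest under the chessboard metric, by 8-neighbour distance
#' propagation), and the resulting piecewise-constant surface is Gaussian
#' smoothed.  Both steps are convex combinations of the masked values, so the
#' envelope always lies within their range.
#'
#' @param image Numeric matrix.
#' @param mask Logical matrix of the same size marking the sample sites;
#'   must contain at least one `TRUE`.
#' @param smooth_sigma Gaussian smoothing std in pixels; `NULL` uses half the
#'   mean spacing `d = sqrt(npix / nsites)` of the sites.
#' @return The envelope matrix.
#' @export
compute_envelope <- function(image, mask, smooth_sigma = NULL) {
  assert_image(image)
  assert_same_size(image, mask, "image and mask")
  nsites <- sum(mask)
  if (nsites == 0L)
    stop("empty mask: no extrema to build an envelope from", call. = FALSE)
  filled <- nn_fill(image, mask)
  if (is.null(smooth_sigma))
    smooth_sigma <- max(1, 0.5 * sqrt(length(image) / nsites))
  gauss_blur(filled, smooth_sigma)
}

# Propagate values of masked sites to all pixels (nearest site under the
# chessboard metric).  Grassfire sweep: each pass extends the filled front by
# one pixel in all 8 directions; converges in at most max-gap passes.
nn_fill <- function(image, mask) {
  n <- nrow(image); m <- ncol(image)
  val <- ifelse(mask, image, 0)
  dist <- ifelse(mask, 0, Inf)
  while (any(is.infinite(dist))) {
    vp <- matrix(0, n + 2L, m + 2L); vp[2:(n + 1L), 2:(m + 1L)] <- val
    dp <- matrix(Inf, n + 2L, m + 2L); dp[2:(n + 1L), 2:(m + 1L)] <- dist
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rows <- (2L + dr):(n + 1L + dr); cols <- (2L + dc):(m + 1L + dc)
      cand <- dp[rows, cols, drop = FALSE] + 1
      better <- cand < dist
      if (any(better)) {
        val[better] <- vp[rows, cols, drop = FALSE][better]
        dist[better] <- cand[better]
      }
    }
  }
  val
}

#' Extract one intrinsic mode function by sifting
#'
#' Standard sifting loop: repeatedly subtract the mean of the upper and lower
#' envelopes, `h <- h - (upper + lower)/2`, until the normalized squared
#' change drops below `sd_tol` or `max_sift_iters` is reached.  The remainder
#' is defined by exact subtraction, `remainder = band - imf`, so
#' `imf + remainder` always reproduces the input bit for bit.
#'
#' @param band Numeric matrix (one high-frequency sub-band).
#' @param params A [sift_params()] object.
#' @return A list with `imf`, `remainder`, and `n_iters` (sifting iterations
#'   actually used; 0 when the band had too few extrema and was returned
#'   entirely as remainder).
#' @export
sift_imf <- function(band, params = sift_params()) {
  assert_image(band)
  h <- band
  n_iters <- 0L
  repeat {
    ex <- find_extrema(h)
    if (sum(ex$maxima) + sum(ex$minima) < params$min_extrema ||
        sum(ex$maxima) == 0L || sum(ex$minima) == 0L) {
      if (n_iters == 0L) h <- matrix(0, nrow(band), ncol(band))
      break
    }
    if (n_iters >= params$max_sift_iters) break
    upper <- compute_envelope(h, ex$maxima, params$envelope_smooth_sigma)
    lower <- compute_envelope(h, ex$minima, params$envelope_smooth_sigma)
    h_new <- h - (upper + lower) / 2
    n_iters <- n_iters + 1L
    sd_val <- sum((h_new - h)^2) / max(sum(h^2), .Machine$double.eps)
    h <- h_new
    if (sd_val < params$sd_tol) break
  }
  list(imf = h, remainder = band - h, n_iters = n_iters)
}

#' Two-IMF bidimensional empirical mode decomposition
#'
#' Decomposes a high-frequency sub-band into exactly two intrinsic mode
#' functions and a residue: `imf1` is sifted from the band, `imf2` from what
#' remains, and `residue = band - imf1 - imf2` by exact subtraction, so the
#' completeness identity holds to machine precision on any input.  Degenerate
#' bands (too few extrema) yield zero IMFs and pass through as residue.
#'
#' @inheritParams sift_imf
#' @return An object of class `emd_result`: list with `imf1`, `imf2`,
#'   `residue`, `n_sift_iters` (length-2 integer vector).
#' @export
#' @examples
#' b <- matrix(rnorm(32 * 32), 32, 32)
#' e <- bemd2(b)
#' max(abs(e$imf1 + e$imf2 + e$residue - b))   # 0
bemd2 <- function(band, params = sift_params()) {
  s1 <- sift_imf(band, params)
  s2 <- sift_imf(s1$remainder, params)
  structure(list(imf1 = s1$imf, imf2 = s2$imf,
                 residue = band - s1$imf - s2$imf,
                 n_sift_iters = c(s1$n_iters, s2$n_iters)),
            class = "emd_result")
}

#' @export
print.emd_result <- function(x, ...) {
  cat(sprintf("BEMD result: %s, sift iterations %s\n",
              paste(dim(x$imf1), collapse = "x"),
              paste(x$n_sift_iters, collapse = " + ")))
  invisible(x)
}
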