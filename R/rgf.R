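#' Rolling guidance filter parameters
#'
#' Parameter bundle for the edge-preserving smoothing stage: a Gaussian
#' pre-filter followed by `n_iter` joint bilateral stages whose range weights
#' are computed on the previous iterate.
#'
#' @param sigma_s Spatial standard deviation in pixels (> 0).
#' @param sigma_r Range standard deviation on the \[0,1\] intensity scale
#'   (> 0).  Small values preserve edges sharply; very large values reduce
#'   the joint bilateral filter to a plain Gaussian.
#' @param n_iter Number of joint bilateral stages (>= 0); 0 gives the
#'   Gaussian pre-filter alone.
#' @param radius Window half-width in pixels; defaults to `ceiling(3*sigma_s)`
#'   which captures essentially all Gaussian mass.
#' @return An object of class `rgf_params`.
#' @export
#' @examples
#' p <- rgf_params(sigma_s = 3, sigma_r = 0.1, n_iter = 4)
rgf_params <- function(sigma_s = 3, sigma_r = 0.1, n_iter = 4L,
                       radius = ceiling(3 * sigma_s)) {
  stopifnot(sigma_s > 0, sigma_r > 0, n_iter >= 0, radius >= 1)
  structure(list(sigma_s = sigma_s, sigma_r = sigma_r,
                 n_iter = as.integer(n_iter), radius = as.integer(radius)),
            class = "rgf_params")
}

#' Windowed normalized Gaussian filter
#'
#' Each output pixel is the weighted average of its square neighbourhood with
#' Gaussian spatial weights, the weights renormalized within the window.
#' Boundaries are handled by symmetric reflection.
#'
#' @param image Numeric matrix, the image to smooth.
#' @param params An [rgf_params()] object (only `sigma_s` and `radius` are
#'   used).
#' @return A matrix of the same size.
#' @export
gaussian_smooth <- function(image, params = rgf_params()) {
  assert_image(image)
  convolve_sep(image, gauss_kernel(params$sigma_s, params$radius))
}

#' Joint bilateral filter
#'
#' Windowed normalized average of `image` where the weight of each neighbour
#' combines a Gaussian spatial term with a Gaussian range term computed on a
#' `guide` image: neighbours whose guide value differs strongly from the
#' centre's guide value are down-weighted, so edges present in the guide are
#' preserved in the output.
#'
#' @param image Matrix to filter.
#' @param guide Matrix of identical size supplying the range differences.
#' @param params An [rgf_params()] object.
#' @return Filtered matrix of the same size.
#' @export
joint_bilateral <- function(image, guide, params = rgf_params()) {
  assert_image(image); assert_image(guide)
  assert_same_size(image, guide, "image and guide")
  r <- params$radius
  n <- nrow(image); m <- ncol(image)
  ip <- pad_reflect(image, r)
  gp <- pad_reflect(guide, r)
  inv2ss <- 1 / (2 * params$sigma_s^2)
  inv2sr <- 1 / (2 * params$sigma_r^2)
  num <- matrix(0, n, m); den <- matrix(0, n, m)
  for (dr in -r:r) {
    rows <- (1L + r + dr):(n + r + dr)
    for (dc in -r:r) {
      cols <- (1L + r + dc):(m + r + dc)
      w <- exp(-(dr * dr + dc * dc) * inv2ss -
                 (guide - gp[rows, cols, drop = FALSE])^2 * inv2sr)
      num <- num + w * ip[rows, cols, drop = FALSE]
      den <- den + w
    }
  }
  num / den
}

#' Rolling guidance filter
#'
#' Removes small-scale structures while recovering large-scale edges: a
#' Gaussian filter produces the first guide `J1`, then the input is joint
#' bilaterally filtered `n_iter` times, each stage guided by the previous
#' output.  Sharpness of retained edges increases with each stage.
#'
#' @inheritParams gaussian_smooth
#' @return `J_{n_iter+1}`, a matrix of the same size.
#' @export
#' @examples
#' x <- matrix(rep(c(0, 1), each = 32 * 64), 64, 64)
#' y <- rolling_guidance(x, rgf_params(sigma_s = 2, sigma_r = 0.1, n_iter = 2))
rolling_guidance <- function(image, params = rgf_params()) {
  assert_image(image)
  j <- gaussian_smooth(image, params)
  if (params$n_iter > 0L) for (k in seq_len(params$n_iter))
    j <- joint_bilateral(image, j, params)
  j
}
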