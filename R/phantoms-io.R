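# Image I/O and the synthetic co-registered MRI/PET phantom generator.
#
# Grayscale images are numeric matrices (rows = image rows) on [0,1];
# color images are height x width x 3 arrays (RGB) on [0,1].

#' Read an image file
#'
#' Reads PNG, TIFF or JPEG through EBImage, rescales to the internal \[0,1\]
#' float scale, and collapses 3-channel files whose channels are identical
#' (gray stored as RGB) to a grayscale matrix.  An alpha channel, if present,
#' is dropped.
#'
#' @param path Path to the image file.
#' @return A grayscale matrix or an RGB array `height x width x 3`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 2L) return(clamp01(t(img)))
  nc <- dim(img)[3L]
  if (nc == 4L) { img <- img[, , 1:3, drop = FALSE]; nc <- 3L }
  if (nc == 2L) { img <- img[, , 1L, drop = FALSE]; nc <- 1L }  # gray+alpha
  if (nc == 1L) return(clamp01(t(img[, , 1L])))
  if (nc != 3L) stop("unsupported channel count: ", nc, call. = FALSE)
  out <- aperm(img, c(2L, 1L, 3L))
  if (identical(out[, , 1L], out[, , 2L]) && identical(out[, , 1L], out[, , 3L]))
    return(clamp01(out[, , 1L]))
  clamp01(out)
}

#' Write an image file
#'
#' Writes a grayscale matrix or RGB array to PNG/TIFF/JPEG (format chosen
#' from the file extension), quantized to 8 bits, so a load/save round trip
#' agrees with the original within 1/255 per pixel.
#'
#' @param path Output path; the parent directory must exist.
#' @param image Grayscale matrix or RGB array on \[0,1\].
#' @export
save_image <- function(path, image) {
  if (!dir.exists(dirname(path)))
    stop("output directory does not exist: ", dirname(path), call. = FALSE)
  if (is.matrix(image)) {
    assert_image(image)
    obj <- EBImage::Image(t(clamp01(image)))
  } else {
    stopifnot(length(dim(image)) == 3L, dim(image)[3L] == 3L)
    obj <- EBImage::Image(aperm(clamp01(image), c(2L, 1L, 3L)),
                          colormode = "Color")
  }
  EBImage::writeImage(obj, path, bits.per.sample = 8L, quality = 100)
  invisible(NULL)
}

#' Extract one axial slice of a NIfTI volume as a grayscale image
#'
#' @param path Path to a `.nii` / `.nii.gz` file (requires the RNifti
#'   package).
#' @param slice Axial slice index (third dimension).
#' @return Grayscale matrix, min-max rescaled to \[0,1\].
#' @export
load_nifti_slice <- function(path, slice) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI requires the RNifti package", call. = FALSE)
  vol <- RNifti::readNifti(path)
  stopifnot(length(dim(vol)) >= 3L, slice >= 1L, slice <= dim(vol)[3L])
  sl <- vol[, , slice]
  rng <- range(sl)
  if (diff(rng) == 0) return(matrix(0, nrow(sl), ncol(sl)))
  (sl - rng[1L]) / diff(rng)
}

# Fixed full-range BT.601 luma/chroma matrix (luma weights 0.299/0.587/0.114).
.ycc_fwd <- rbind(y  = c(0.299, 0.587, 0.114),
                  cb = 0.564 * c(-0.299, -0.587, 1 - 0.114),
                  cr = 0.713 * c(1 - 0.299, -0.587, -0.114))
.ycc_inv <- solve(.ycc_fwd)

#' Split a color image into luma and chroma planes
#'
#' Luma is the standard BT.601 luminance weighting of RGB
#' (0.299 R + 0.587 G + 0.114 B); the two chroma planes are the scaled
#' blue- and red-difference components.  The transform is linear and exactly
#' invertible by [merge_luma_chroma()].
#'
#' @param image RGB array `height x width x 3` on \[0,1\].
#' @return List with `luma` (matrix) and `chroma` (array `h x w x 2`,
#'   planes Cb and Cr, zero for achromatic pixels).
#' @export
split_luma_chroma <- function(image) {
  stopifnot(is.array(image), length(dim(image)) == 3L, dim(image)[3L] == 3L)
  d <- dim(image)
  rgb <- matrix(image, ncol = 3L)
  ycc <- rgb %*% t(.ycc_fwd)
  list(luma = matrix(ycc[, 1L], d[1L], d[2L]),
       chroma = array(ycc[, 2:3], c(d[1L], d[2L], 2L)))
}

#' Recombine luma and chroma planes into a color image
#'
#' Exact inverse of [split_luma_chroma()]; out-of-gamut values produced by
#' replacing the luma plane (e.g. with a fused one) are clipped into \[0,1\].
#'
#' @param luma Grayscale matrix.
#' @param chroma Array `height x width x 2` (Cb, Cr planes).
#' @return RGB array `height x width x 3` on \[0,1\].
#' @export
merge_luma_chroma <- function(luma, chroma) {
  stopifnot(is.array(chroma), length(dim(chroma)) == 3L, dim(chroma)[3L] == 2L)
  assert_image(luma)
  if (!identical(dim(luma), dim(chroma)[1:2]))
    stop("luma and chroma sizes differ", call. = FALSE)
  ycc <- cbind(as.vector(luma), matrix(chroma, ncol = 2L))
  rgb <- ycc %*% t(.ycc_inv)
  clamp01(array(rgb, c(dim(luma), 3L)))
}

#' Specification of a synthetic MRI/PET phantom pair
#'
#' Bundles the parameters of the seeded phantom generator.  Defaults emulate
#' the statistical structure of co-registered brain MRI/PET slice pairs:
#' a handful of nested elliptical "anatomical" regions shared by both
#' modalities, fine band-limited texture visible only in the MRI, a smooth
#' functional hotspot visible only in the PET, and independent additive
#' noise per modality.
#'
#' @param shape Integer vector `c(height, width)`, both >= 16.
#' @param n_structures Number of nested elliptical regions (3-6 is typical).
#' @param texture_amp Amplitude of the MRI fine texture on the \[0,1\] scale.
#' @param hotspot_sigma Gaussian radius (pixels) of the PET hotspot.
#' @param hotspot_amp Peak amplitude of the PET hotspot.
#' @param noise_sigma Std of the additive Gaussian noise added independently
#'   to each modality (>= 0).
#' @param seed Integer seed fixing the pair exactly.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L), n_structures = 4L,
                         texture_amp = 0.06, hotspot_sigma = 6,
                         hotspot_amp = 0.5, noise_sigma = 0.01, seed = 1L) {
  if (any(shape < 16L))
    stop("phantom shape must be at least 16 x 16 pixels", call. = FALSE)
  stopifnot(n_structures >= 1, noise_sigma >= 0, hotspot_sigma > 0,
            texture_amp >= 0, hotspot_amp >= 0)
  structure(list(shape = as.integer(shape),
                 n_structures = as.integer(n_structures),
                 texture_amp = texture_amp, hotspot_sigma = hotspot_sigma,
                 hotspot_amp = hotspot_amp, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Fixed "hot-iron" pseudo-color map used to render PET functional intensity.
pet_colormap <- function(v) {
  r <- clamp01(3 * v)
  g <- clamp01(3 * v - 1)
  b <- clamp01(3 * v - 2)
  array(c(r, g, b), c(dim(v), 3L))
}

#' Generate a co-registered synthetic MRI/PET phantom pair
#'
#' Builds the shared anatomy as `n_structures` nested ellipses (identical
#' region-label masks for both modalities, i.e. perfectly co-registered).
#' The MRI paints each region with a distinct intensity, adds band-limited
#' high-frequency texture inside the head, and additive Gaussian noise.
#' The PET functional image paints regions with independent smooth uptake
#' levels, blurs them (low PET spatial resolution), adds a Gaussian hotspot
#' overlapping one structure plus noise, and renders the result through a
#' fixed pseudo-color map.
#'
#' All randomness is routed through `spec$seed`; the same spec reproduces
#' the pair bitwise.
#'
#' @param spec A [phantom_spec()] object.
#' @return List with `mri` (matrix), `pet` (RGB array), `pet_luma` (the
#'   functional intensity before colorization), `labels` (integer region
#'   mask) and `spec`.
#' @export
#' @examples
#' p <- generate_phantom_pair(phantom_spec(seed = 7))
#' str(p$mri)
generate_phantom_pair <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, {
    h <- spec$shape[1L]; w <- spec$shape[2L]
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)

    # nested ellipses: label = number of ellipses containing the pixel
    labels <- matrix(0L, h, w)
    cy <- h / 2 + stats::runif(1, -0.05, 0.05) * h
    cx <- w / 2 + stats::runif(1, -0.05, 0.05) * w
    scale <- seq(0.42, 0.10, length.out = spec$n_structures)
    for (k in seq_len(spec$n_structures)) {
      ay <- scale[k] * h * stats::runif(1, 0.85, 1.15)
      ax <- scale[k] * w * stats::runif(1, 0.85, 1.15)
      ocy <- cy + stats::runif(1, -0.03, 0.03) * h * (k - 1)
      ocx <- cx + stats::runif(1, -0.03, 0.03) * w * (k - 1)
      phi <- stats::runif(1, 0, pi)
      dy <- yy - ocy; dx <- xx - ocx
      u <- cos(phi) * dx + sin(phi) * dy
      v <- -sin(phi) * dx + cos(phi) * dy
      inside <- (u / ax)^2 + (v / ay)^2 <= 1
      labels[inside] <- labels[inside] + 1L
    }

    # MRI: piecewise-constant anatomy + fine texture inside the head + noise
    mri_levels <- c(0.05, sample(seq(0.25, 0.9, length.out = spec$n_structures)))
    mri <- matrix(mri_levels[labels + 1L], h, w)
    if (spec$texture_amp > 0) {
      noise <- matrix(stats::rnorm(h * w), h, w)
      texture <- noise - gauss_blur(noise, 2)        # band-limited (high-pass)
      texture <- texture / stats::sd(texture)
      mri <- mri + spec$texture_amp * texture * (labels >= 1L)
    }
    if (spec$noise_sigma > 0)
      mri <- mri + matrix(stats::rnorm(h * w, sd = spec$noise_sigma), h, w)
    mri <- clamp01(mri)

    # PET: smooth uptake per region + hotspot + noise, then pseudo-color
    pet_levels <- c(0.02, stats::runif(spec$n_structures, 0.2, 0.7))
    pet_base <- gauss_blur(matrix(pet_levels[labels + 1L], h, w), 3)
    pet_luma <- pet_base
    if (spec$hotspot_amp > 0) {
      inner <- which(labels == max(labels), arr.ind = TRUE)
      ctr <- inner[sample(nrow(inner), 1L), ]
      blob <- exp(-((yy - ctr[1L])^2 + (xx - ctr[2L])^2) /
                    (2 * spec$hotspot_sigma^2))
      pet_luma <- pet_luma + spec$hotspot_amp * blob
    }
    if (spec$noise_sigma > 0)
      pet_luma <- pet_luma +
        matrix(stats::rnorm(h * w, sd = spec$noise_sigma), h, w)
    pet_luma <- clamp01(pet_luma)

    list(mri = mri, pet = pet_colormap(pet_luma), pet_luma = pet_luma,
         labels = labels, spec = spec)
  })
}
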