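#' Laplacian-pyramid band split into two high bands and one low band
#'
#' Decomposes an image `X` into a fixed three-band set: two high-frequency
#' sub-bands `h1` (finest), `h2`, and a low-frequency sub-band `low`.
#'
#' In the default `"undecimated"` mode the bands are a difference-of-Gaussians
#' stack at full resolution: `h1 = X - G1(X)`, `h2 = G1(X) - G2(X)`,
#' `low = G2(X)` with `Gk` a Gaussian blur of standard deviation `sigmak`.
#' The telescoping sum `h1 + h2 + low` then reproduces `X` to machine
#' precision and all bands share the source's size, which is what the
#' downstream fusion stages assume.
#'
#' In `"decimated"` mode the classic Burt-Adelson pyramid (5-tap kernel,
#' a = 0.375, reflect borders) is used with two detail levels: `h1` at full
#' resolution, `h2` at half, `low` at quarter resolution, and
#' [lp_reconstruct()] inverts by expand-and-add.
#'
#' @param image Numeric matrix, at least 16 pixels on each side.
#' @param sigma1,sigma2 Gaussian scales of the band edges (undecimated mode);
#'   requires `sigma2 > sigma1 > 0`.
#' @param mode `"undecimated"` (default) or `"decimated"`.
#' @return An object of class `bandset`: a list with elements `h1`, `h2`,
#'   `low`, `mode`, `sigma1`, `sigma2`.
#' @seealso [lp_reconstruct()]
#' @export
#' @examples
#' x <- matrix(runif(64 * 64), 64, 64)
#' b <- lp_decompose(x)
#' max(abs(b$h1 + b$h2 + b$low - x))   # ~ 1e-16
lp_decompose <- function(image, sigma1 = 1, sigma2 = 4,
                         mode = c("undecimated", "decimated")) {
  mode <- match.arg(mode)
  assert_image(image, min_side = 16L)
  if (mode == "undecimated") {
    stopifnot(sigma1 > 0, sigma2 > sigma1)
    g1 <- gauss_blur(image, sigma1)
    g2 <- gauss_blur(image, sigma2)
    bands <- list(h1 = image - g1, h2 = g1 - g2, low = g2)
  } else {
    g1 <- pyr_reduce(image)
    g2 <- pyr_reduce(g1)
    bands <- list(h1 = image - pyr_expand(g1, dim(image)),
                  h2 = g1 - pyr_expand(g2, dim(g1)),
                  low = g2)
  }
  structure(c(bands, list(mode = mode, sigma1 = sigma1, sigma2 = sigma2)),
            class = "bandset")
}

#' Reconstruct an image from its three-band set
#'
#' Exact inverse of [lp_decompose()]: a direct pixel-wise sum in undecimated
#' mode, expand-and-add through the pyramid in decimated mode.
#'
#' @param bands A `bandset` as returned by [lp_decompose()].
#' @return The reconstructed image matrix.
#' @export
lp_reconstruct <- function(bands) {
  stopifnot(inherits(bands, "bandset"))
  if (bands$mode == "undecimated") {
    assert_same_size(bands$h1, bands$h2, "bands")
    assert_same_size(bands$h1, bands$low, "bands")
    bands$h1 + bands$h2 + bands$low
  } else {
    g1 <- pyr_expand(bands$low, dim(bands$h2)) + bands$h2
    pyr_expand(g1, dim(bands$h1)) + bands$h1
  }
}

#' @export
print.bandset <- function(x, ...) {
  cat(sprintf("Laplacian band set (%s): h1 %s, h2 %s, low %s\n", x$mode,
              paste(dim(x$h1), collapse = "x"),
              paste(dim(x$h2), collapse = "x"),
              paste(dim(x$low), collapse = "x")))
  invisible(x)
}

# Burt-Adelson generating kernel, a = 0.375.
burt_kernel <- function() c(0.0625, 0.25, 0.375, 0.25, 0.0625)

# Blur + 2x downsample (odd-indexed rows/cols kept).
pyr_reduce <- function(x) {
  s <- convolve_sep(x, burt_kernel())
  s[seq.int(1L, nrow(x), by = 2L), seq.int(1L, ncol(x), by = 2L), drop = FALSE]
}

# Zero-upsample to `target_dim` then blur with the doubled kernel.
pyr_expand <- function(x, target_dim) {
  up <- matrix(0, target_dim[1L], target_dim[2L])
  up[seq.int(1L, by = 2L, length.out = nrow(x)),
     seq.int(1L, by = 2L, length.out = ncol(x))] <- x
  convolve_sep(up, 2 * burt_kernel())
}
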