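# Internal numerics shared by the filtering, pyramid and metric code.
# Images are plain numeric matrices, row = image row (y), col = x,
# intensities on the [0,1] scale unless a function states otherwise.

#' @keywords internal
assert_image <- function(x, name = deparse(substitute(x)), min_side = 1L) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  if (nrow(x) < min_side || ncol(x) < min_side)
    stop(sprintf("`%s` must be at least %d x %d pixels", name, min_side, min_side),
         call. = FALSE)
  invisible(x)
}

#' @keywords internal
assert_same_size <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must have identical dimensions (%s vs %s)",
                 what, paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  invisible(NULL)
}

# Symmetric (reflect) index vector for length n extended by r on each side.
# Reflection repeats the border pixel (edge-inclusive), and folds back and
# forth when r exceeds n so arbitrary pad widths stay valid.
reflect_index <- function(n, r) {
  if (n == 1L) return(rep(1L, n + 2L * r))
  period <- 2L * n
  i <- seq.int(1L - r, n + r)
  j <- ((i - 1L) %% period) + 1L          # 1 .. 2n
  j[j > n] <- period - j[j > n] + 1L      # fold upper half back
  j
}

# Reflect-pad a matrix by r rows/cols on every side.
pad_reflect <- function(x, r) {
  if (r == 0L) return(x)
  x[reflect_index(nrow(x), r), reflect_index(ncol(x), r), drop = FALSE]
}

# Normalized 1-D Gaussian kernel, truncated at `radius`.
gauss_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  stopifnot(sigma > 0, radius >= 0)
  k <- exp(-(seq.int(-radius, radius))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable correlation of `x` with a (symmetric) 1-D kernel along rows then
# columns, reflect-padded.  With a normalized kernel this equals the windowed
# normalized filter with Gaussian weights, because the 2-D weight sum
# factorizes into the product of the 1-D sums.
convolve_sep <- function(x, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(x * kernel)
  n <- nrow(x); m <- ncol(x)
  # rows (vertical pass)
  p <- x[reflect_index(n, r), , drop = FALSE]
  acc <- matrix(0, n, m)
  for (k in seq_along(kernel))
    acc <- acc + kernel[k] * p[k:(k + n - 1L), , drop = FALSE]
  # columns (horizontal pass)
  p <- acc[, reflect_index(m, r), drop = FALSE]
  acc <- matrix(0, n, m)
  for (k in seq_along(kernel))
    acc <- acc + kernel[k] * p[, k:(k + m - 1L), drop = FALSE]
  acc
}

# Gaussian blur with reflect boundaries (the workhorse smoother).
gauss_blur <- function(x, sigma, radius = ceiling(3 * sigma)) {
  convolve_sep(x, gauss_kernel(sigma, radius))
}

# Separable running maximum / minimum over a (2r+1)^2 square window,
# reflect-padded (used for morphological helpers).
window_extremum <- function(x, r, which = c("max", "min")) {
  which <- match.arg(which)
  fun <- if (which == "max") pmax else pmin
  n <- nrow(x); m <- ncol(x)
  p <- x[reflect_index(n, r), , drop = FALSE]
  acc <- p[1:n, , drop = FALSE]
  if (r > 0L) for (k in 2:(2L * r + 1L))
    acc <- fun(acc, p[k:(k + n - 1L), , drop = FALSE])
  p <- acc[, reflect_index(m, r), drop = FALSE]
  acc <- p[, 1:m, drop = FALSE]
  if (r > 0L) for (k in 2:(2L * r + 1L))
    acc <- fun(acc, p[, k:(k + m - 1L), drop = FALSE])
  acc
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
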