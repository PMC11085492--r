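#' Configuration for Stage 1 gray-level quantization
#'
#' Stage 1 maps an 8-bit image into a fixed gray band `[Gn, Gn + Gm]` with a
#' bounded exponential (improved Gamma) transform applied to a min-max
#' normalized, Gaussian-smoothed copy of the input.
#'
#' @param r Exponent of the bounded exponential transform. `r > 1` darkens
#'   bright images, `0 < r < 1` brightens dark ones. `NULL` (default) selects
#'   `r` automatically per image so that the mean of the blurred normalized
#'   image maps to the middle of the band; the selected value is clamped to
#'   `[0.5, 3]`.
#' @param Gm Span of the output gray band, in gray levels.
#' @param Gn Lower bound (offset) of the output band, in gray levels.
#'   `Gn + Gm` must stay within 8-bit range. A positive `Gn` also keeps the
#'   Stage-2 regional light estimate strictly positive.
#' @param sigma Standard deviation of the Gaussian smoothing kernel, pixels.
#' @param kernel_radius Truncation radius of the kernel, pixels; the default
#'   `ceiling(3 * sigma)` captures over 99 percent of the kernel mass.
#' @return An object of class `gray_quant_config`.
#' @export
gray_quant_config <- function(r = NULL, Gm = 200, Gn = 30, sigma = 1.5,
                              kernel_radius = ceiling(3 * sigma)) {
  if (!is.null(r) && (length(r) != 1L || !is.finite(r) || r <= 0))
    stopf("'r' must be NULL or a single positive number")
  if (Gm <= 0) stopf("'Gm' must be positive")
  if (Gn < 0) stopf("'Gn' must be non-negative")
  if (Gn + Gm > 255) stopf("'Gn + Gm' must not exceed 255")
  if (sigma <= 0) stopf("'sigma' must be positive")
  if (kernel_radius < 1) stopf("'kernel_radius' must be at least 1")
  structure(list(r = r, Gm = Gm, Gn = Gn, sigma = sigma,
                 kernel_radius = as.integer(kernel_radius)),
            class = "gray_quant_config")
}

#' Min-max normalize an image to the unit interval
#'
#' Rescales gray values by the image's own minimum and maximum so the output
#' spans exactly `[0, 1]`. The map is affine and therefore strictly
#' order-preserving.
#'
#' @param image Numeric matrix of gray values.
#' @return Numeric matrix with minimum 0 and maximum 1.
#' @export
minmax_normalize <- function(image) {
  check_image(image)
  lo <- min(image); hi <- max(image)
  if (hi == lo)
    stopf("degenerate input: image is constant (all pixels equal %g), cannot min-max normalize", lo)
  (image - lo) / (hi - lo)
}

# Normalized 1-D Gaussian taps at offsets -radius..radius.
gaussian_taps <- function(sigma, radius) {
  u <- seq.int(-radius, radius)
  g <- exp(-u^2 / (2 * sigma^2))
  g / sum(g)
}

#' Gaussian smoothing with reflected borders
#'
#' Convolves with a normalized isotropic Gaussian kernel of standard
#' deviation `sigma`, truncated at `kernel_radius`, using reflect padding.
#' The 2-D kernel is separable, and per-axis normalization of the 1-D taps
#' is identical to normalizing the truncated 2-D kernel to unit sum.
#'
#' @param image Numeric matrix (any gray scale; values are only smoothed).
#' @param config A [gray_quant_config()].
#' @return Smoothed matrix of the same shape.
#' @export
gaussian_blur <- function(image, config = gray_quant_config()) {
  check_image(image)
  stopifnot(inherits(config, "gray_quant_config"))
  r <- config$kernel_radius
  g <- gaussian_taps(config$sigma, r)
  nr <- nrow(image); nc <- ncol(image)
  # rows pass
  pad <- image[reflect_indices(nr, r), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (k in seq_along(g))
    out <- out + g[k] * pad[seq_len(nr) + (k - 1L), , drop = FALSE]
  # cols pass
  pad <- out[, reflect_indices(nc, r), drop = FALSE]
  out <- matrix(0, nr, nc)
  for (k in seq_along(g))
    out <- out + g[k] * pad[, seq_len(nc) + (k - 1L), drop = FALSE]
  out
}

#' Bounded exponential gray transform
#'
#' Applies `Wg = G1^r * Gm + Gn` elementwise, mapping the unit interval into
#' the band `[Gn, Gn + Gm]`. Monotone non-decreasing in the input for any
#' `r > 0`; exactly affine when `r = 1`.
#'
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param config A [gray_quant_config()]; `config$r` must be set.
#' @return Matrix with values in `[Gn, Gn + Gm]`.
#' @export
bounded_exponential_transform <- function(image, config = gray_quant_config(r = 1)) {
  check_image(image)
  stopifnot(inherits(config, "gray_quant_config"))
  if (is.null(config$r))
    stopf("'r' is unset; supply a fixed r or use quantize_gray() for automatic selection")
  if (min(image) < 0 || max(image) > 1)
    stopf("input to the exponential transform must lie in [0, 1]")
  out <- image^config$r * config$Gm + config$Gn
  clamp(out, config$Gn, config$Gn + config$Gm)
}

# Auto-select r so the blurred image's mean gray maps to mid-band:
# mean^r = 0.5, clamped to [0.5, 3].
auto_select_r <- function(blurred) {
  m <- mean(blurred)
  if (m <= 0 || m >= 1) return(1)
  clamp(log(0.5) / log(m), 0.5, 3)
}

#' Stage 1: quantize gray values into a fixed band
#'
#' Composition of [minmax_normalize()], [gaussian_blur()] and
#' [bounded_exponential_transform()]. When `config$r` is `NULL` the exponent
#' is chosen per image (see [gray_quant_config()]) and recorded in the
#' result's `"r"` attribute.
#'
#' @param image Numeric matrix of 8-bit gray values with at least two
#'   distinct levels.
#' @param config A [gray_quant_config()].
#' @return Matrix with values in `[Gn, Gn + Gm]`, attribute `"r"` holding the
#'   exponent actually used.
#' @export
quantize_gray <- function(image, config = gray_quant_config()) {
  stopifnot(inherits(config, "gray_quant_config"))
  g1 <- gaussian_blur(minmax_normalize(image), config)
  # smoothing of [0,1] data is bounded but guard against roundoff
  g1 <- clamp(g1, 0, 1)
  r <- if (is.null(config$r)) auto_select_r(g1) else config$r
  cfg <- config
  cfg$r <- r
  out <- bounded_exponential_transform(g1, cfg)
  attr(out, "r") <- r
  out
}
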