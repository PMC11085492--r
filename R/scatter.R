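#' Configuration for Stage 2 scattering-model restoration
#'
#' Stage 2 treats the quantized image as the observation `I` of the
#' transmission scattering model `I = J * eps + A * (1 - eps)`, where `J` is
#' the latent (restored) image, `eps` the local tissue absorption rate and
#' `A` the regional incident light intensity. `eps` is estimated with the
#' pixel-mutation filter over two nested square windows `Omega2` (inner,
#' vein-scale) and `Omega1` (outer, illumination-scale), and `A` as the mean
#' of the brightest pixels in the outer window.
#'
#' @param omega1 Odd side length of the outer window, pixels. Should be large
#'   enough to capture regional illumination; default 31.
#' @param omega2 Odd side length of the inner window, pixels. Should exceed
#'   the typical vein stroke width; default 7. Must be smaller than `omega1`.
#' @param top_fraction Fraction of brightest pixels in the outer window
#'   averaged to estimate `A`; the regional-light rule fixes this at 0.05.
#' @param eps_min Lower clamp for the absorption rate. Bounds the noise
#'   amplification of the model inversion (the restored value scales with
#'   `1 / eps`); default 0.1.
#' @return An object of class `scatter_config`.
#' @export
scatter_config <- function(omega1 = 31, omega2 = 7, top_fraction = 0.05,
                           eps_min = 0.1) {
  omega1 <- check_odd_window(omega1, "omega1")
  omega2 <- check_odd_window(omega2, "omega2")
  if (omega2 >= omega1) stopf("'omega2' (%d) must be smaller than 'omega1' (%d)",
                              omega2, omega1)
  if (top_fraction <= 0 || top_fraction > 1)
    stopf("'top_fraction' must be in (0, 1]")
  if (eps_min <= 0 || eps_min >= 1)
    stopf("'eps_min' must be in (0, 1)")
  structure(list(omega1 = omega1, omega2 = omega2,
                 top_fraction = top_fraction, eps_min = eps_min),
            class = "scatter_config")
}

#' Pixel-mutation filter (FMP)
#'
#' For every pixel, with `mx2` and `mx1` the maxima over the inner and outer
#' windows centred there, and `C` the fraction of outer-window pixels not
#' larger than the centre value (ties counted in), computes
#' `FMP = mx2 + N * min(C * (mx1 - mx2), mx1)` where `N` is `+1` when
#' `C >= count(Omega2) / count(Omega1)` and `-1` otherwise. The result is
#' floored at 0. Windows are reflect-padded at borders.
#'
#' The filter tracks the local maximum but pulls the estimate down at pixels
#' whose value is low in the regional rank order (vein interiors), which
#' accentuates gray-value mutations at vein borders.
#'
#' @param image Numeric matrix (typically the Stage-1 output).
#' @param config A [scatter_config()].
#' @return Matrix of filtered values, same shape, all `>= 0`.
#' @export
fmp_filter <- function(image, config = scatter_config()) {
  check_image(image)
  stopifnot(inherits(config, "scatter_config"))
  if (nrow(image) < config$omega2 || ncol(image) < config$omega2)
    stopf("image (%dx%d) is smaller than the inner window (%d)",
          nrow(image), ncol(image), config$omega2)
  mx1 <- cpp_local_max(image, config$omega1)
  mx2 <- cpp_local_max(image, config$omega2)
  C <- cpp_rank_fraction(image, config$omega1)
  ratio <- (config$omega2 / config$omega1)^2
  N <- ifelse(C >= ratio, 1, -1)
  out <- mx2 + N * pmin(C * (mx1 - mx2), mx1)
  pmax(out, 0)
}

#' Regional incident light intensity
#'
#' Estimates the incident light `A(x, y)` at each pixel as the mean of the
#' top `top_fraction` (by default 5 percent, count rounded up) brightest
#' pixels of the outer window centred there, reflect-padded. By construction
#' `A` lies between the windowed mean and the windowed maximum.
#'
#' @param image Numeric matrix.
#' @param config A [scatter_config()].
#' @return Matrix of light intensities, same shape.
#' @export
regional_light_intensity <- function(image, config = scatter_config()) {
  check_image(image)
  stopifnot(inherits(config, "scatter_config"))
  cpp_topfrac_mean(image, config$omega1, config$top_fraction)
}

#' Absorption-rate map
#'
#' The absorption rate is the ratio of outgoing to incident light; with the
#' pixel-mutation filter standing in for the outgoing intensity this is
#' `eps = FMP / A`, clamped into `[eps_min, 1]`.
#'
#' @param fmp Output of [fmp_filter()].
#' @param light Output of [regional_light_intensity()].
#' @param config A [scatter_config()].
#' @return Matrix of absorption rates in `[eps_min, 1]`.
#' @export
absorption_map <- function(fmp, light, config = scatter_config()) {
  check_image(fmp, "fmp"); check_image(light, "light")
  check_same_shape(fmp, light, "fmp", "light")
  stopifnot(inherits(config, "scatter_config"))
  if (any(light <= 0))
    stopf("regional light intensity must be strictly positive everywhere")
  clamp(fmp / light, config$eps_min, 1)
}

#' Invert the scattering model
#'
#' Solves `I = J * eps + A * (1 - eps)` for the latent image:
#' `J = (I - A * (1 - eps)) / eps`, clamped to `[0, 255]`.
#'
#' @param image Observed image `I`.
#' @param light Incident light field `A`.
#' @param eps Absorption map in `[eps_min, 1]`.
#' @return Restored image `J`, values in `[0, 255]`.
#' @export
invert_scattering <- function(image, light, eps) {
  check_image(image); check_image(light, "light"); check_image(eps, "eps")
  check_same_shape(image, light, "image", "light")
  check_same_shape(image, eps, "image", "eps")
  if (any(eps <= 0)) stopf("absorption rates must be strictly positive")
  clamp((image - light * (1 - eps)) / eps, 0, 255)
}

#' Stage 2: restore local vein contrast
#'
#' Composition of [fmp_filter()], [regional_light_intensity()],
#' [absorption_map()] and [invert_scattering()]. Constant images are fixed
#' points (the absorption estimate is exactly 1 there).
#'
#' @param image Numeric matrix, typically the Stage-1 output.
#' @param config A [scatter_config()].
#' @param keep_fields If `TRUE`, attach the intermediate `fmp`, `light` and
#'   `eps` fields as attributes of the result for inspection.
#' @return Restored image in `[0, 255]`.
#' @export
restore_scatter <- function(image, config = scatter_config(),
                            keep_fields = FALSE) {
  fmp <- fmp_filter(image, config)
  light <- regional_light_intensity(image, config)
  eps <- absorption_map(fmp, light, config)
  out <- invert_scattering(image, light, eps)
  if (keep_fields) {
    attr(out, "fmp") <- fmp
    attr(out, "light") <- light
    attr(out, "eps") <- eps
  }
  out
}
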