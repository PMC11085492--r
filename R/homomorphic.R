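#' Configuration for Stage 3 homomorphic normalization
#'
#' Stage 3 filters the log-transformed image in the frequency domain with a
#' Gaussian-type high-emphasis transfer function that attenuates the
#' low-frequency illumination component (gain `rL`) and amplifies
#' high-frequency reflectance detail (gain `rH`).
#'
#' @param D0 Cutoff frequency in frequency-grid units; default 25.
#' @param rH High-frequency gain; default 2.
#' @param rL Low-frequency gain; default 0.5. Must satisfy `rH > rL > 0`.
#' @param c Sharpening coefficient controlling the steepness of the
#'   transition; default 1.
#' @param order Filter order `n`; the radial profile uses
#'   `(D^2 / D0^2)^order`; default 1.
#' @param log_offset Additive guard before the logarithm so zero-valued
#'   pixels are representable. The default equals the 8-bit full scale (255),
#'   i.e. the filter operates on `log(1 + I/255)` up to an additive constant.
#'   A guard much smaller than the gray scale lets the near-zero vein
#'   interiors produced by the Stage-2 clamp dominate the log-domain
#'   spectrum, and the high-frequency emphasis then shreds exactly the
#'   structures the pipeline is meant to preserve.
#' @return An object of class `homomorphic_config`.
#' @export
homomorphic_config <- function(D0 = 25, rH = 2, rL = 0.5, c = 1, order = 1,
                               log_offset = 255) {
  if (!(rH > rL && rL > 0)) stopf("'rH' must exceed 'rL' and both be positive")
  if (D0 <= 0) stopf("'D0' must be positive")
  if (c <= 0) stopf("'c' must be positive")
  if (order < 1) stopf("'order' must be at least 1")
  if (log_offset <= 0) stopf("'log_offset' must be positive")
  structure(list(D0 = D0, rH = rH, rL = rL, c = c, order = as.integer(order),
                 log_offset = log_offset),
            class = "homomorphic_config")
}

#' Homomorphic transfer function
#'
#' Builds `H(u, v) = (rH - rL) * (1 - exp(-c * (D^2 / D0^2)^order)) + rL`
#' on an `height x width` frequency grid with the zero frequency at the
#' geometric centre, `D` being the Euclidean distance to it. `H` is bounded
#' in `[rL, rH]`, equals `rL` at zero frequency, and increases monotonically
#' with `D`.
#'
#' @param height,width Grid dimensions in pixels.
#' @param config A [homomorphic_config()].
#' @return Numeric matrix of gains, zero frequency at the centre.
#' @export
transfer_function <- function(height, width, config = homomorphic_config()) {
  stopifnot(inherits(config, "homomorphic_config"))
  if (height < 1 || width < 1) stopf("grid dimensions must be positive")
  # zero frequency sits on the grid point floor(n / 2) (0-based), the same
  # element the quadrant swap moves to the DFT origin
  u0 <- floor(height / 2)
  v0 <- floor(width / 2)
  d2 <- outer((seq_len(height) - 1 - u0)^2, (seq_len(width) - 1 - v0)^2, "+")
  (config$rH - config$rL) *
    (1 - exp(-config$c * (d2 / config$D0^2)^config$order)) + config$rL
}

# Swap quadrants so the centred transfer function aligns with the
# unshifted DFT layout (zero frequency at element [1, 1]).
ifftshift_mat <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- c(seq.int(floor(nr / 2) + 1L, nr), seq_len(floor(nr / 2)))
  ci <- c(seq.int(floor(nc / 2) + 1L, nc), seq_len(floor(nc / 2)))
  x[ri, ci, drop = FALSE]
}

#' Stage 3: global normalization by homomorphic filtering
#'
#' Pipeline: `log(image + log_offset)`, 2-D Fourier transform, multiply by
#' the centred transfer function, inverse transform (real part), exponentiate
#' and subtract the offset, then min-max rescale to `[0, 255]` and round to
#' 8-bit. A degenerate (constant) filtered image cannot be rescaled and is
#' returned as constant mid-gray 128 with a warning.
#'
#' @param image Numeric matrix with non-negative values (typically the
#'   Stage-2 output in `[0, 255]`).
#' @param config A [homomorphic_config()].
#' @return Integer-valued matrix spanning `[0, 255]`.
#' @export
homomorphic_normalize <- function(image, config = homomorphic_config()) {
  check_image(image)
  stopifnot(inherits(config, "homomorphic_config"))
  if (min(image) < 0) stopf("homomorphic input must be non-negative")
  H <- ifftshift_mat(transfer_function(nrow(image), ncol(image), config))
  lg <- log(image + config$log_offset)
  flt <- Re(stats::fft(stats::fft(lg) * H, inverse = TRUE)) / length(lg)
  out <- exp(flt) - config$log_offset
  lo <- min(out); hi <- max(out)
  if (hi - lo < .Machine$double.eps * max(abs(hi), 1)) {
    warning("filtered image is constant; returning mid-gray 128",
            call. = FALSE)
    return(matrix(128, nrow(image), ncol(image)))
  }
  round((out - lo) / (hi - lo) * 255)
}
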