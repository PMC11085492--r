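# Seeded synthetic vessel phantoms degraded with the same forward scattering
# model the pipeline inverts: I = J * eps + A * (1 - eps), with smooth
# low-frequency absorption and illumination fields and additive sensor noise.

# Evaluate expr with a locally seeded, fixed-algorithm RNG; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Configuration for the synthetic phantom generator
#'
#' The generator emulates ROI-cropped near-infrared finger-vein frames: dark
#' curvilinear vessel strokes with gradient-smooth borders on a bright,
#' gently varying background, degraded by regionally varying illumination and
#' a scattering mixture that collapses vein/non-vein contrast.
#'
#' @param height,width Image dimensions in pixels; default 240 x 320.
#' @param n_vessels Range (length-2) for the number of vessel strokes drawn
#'   per image; default 4 to 8.
#' @param vessel_width Range of stroke widths in pixels; default 3 to 9,
#'   bracketing typical vein projections at this scale.
#' @param vein_depth Range of the gray-level depression of vessel strokes in
#'   the clean image; default 60 to 120.
#' @param severity One of `"mild"`, `"moderate"`, `"severe"`; presets for
#'   `eps_range` and `illum_amplitude` below.
#' @param eps_range Range of the forward absorption field. Presets:
#'   mild `[0.7, 0.95]`, moderate `[0.45, 0.8]`, severe `[0.25, 0.6]`
#'   (smaller values mix more ambient light in, washing out the veins).
#' @param illum_amplitude Relative amplitude of the low-frequency
#'   illumination variation. Presets: mild 0.1, moderate 0.3, severe 0.5.
#' @param noise_sigma Additive Gaussian sensor noise, gray levels; default 2.
#' @param seed Integer seed; every draw is fully determined by it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(height = 240, width = 320,
                         n_vessels = c(4, 8), vessel_width = c(3, 9),
                         vein_depth = c(60, 120),
                         severity = c("moderate", "mild", "severe"),
                         eps_range = NULL, illum_amplitude = NULL,
                         noise_sigma = 2, seed = 0) {
  severity <- match.arg(severity)
  presets <- list(mild = list(eps = c(0.7, 0.95), amp = 0.1),
                  moderate = list(eps = c(0.45, 0.8), amp = 0.3),
                  severe = list(eps = c(0.25, 0.6), amp = 0.5))
  if (is.null(eps_range)) eps_range <- presets[[severity]]$eps
  if (is.null(illum_amplitude)) illum_amplitude <- presets[[severity]]$amp
  if (height < 16 || width < 16) stopf("phantom dimensions must be at least 16")
  if (length(eps_range) != 2L || any(eps_range <= 0) || any(eps_range > 1) ||
      eps_range[1] > eps_range[2])
    stopf("'eps_range' must be an ordered pair within (0, 1]")
  if (length(n_vessels) != 2L || n_vessels[1] > n_vessels[2] || n_vessels[1] < 0)
    stopf("'n_vessels' must be an ordered non-negative pair")
  if (length(vessel_width) != 2L || vessel_width[1] < 1 ||
      vessel_width[1] > vessel_width[2])
    stopf("'vessel_width' must be an ordered pair with minimum >= 1")
  if (length(vein_depth) != 2L || vein_depth[1] > vein_depth[2])
    stopf("'vein_depth' must be an ordered pair")
  if (illum_amplitude < 0) stopf("'illum_amplitude' must be non-negative")
  if (noise_sigma < 0) stopf("'noise_sigma' must be non-negative")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_vessels = n_vessels, vessel_width = vessel_width,
                 vein_depth = vein_depth, severity = severity,
                 eps_range = eps_range, illum_amplitude = illum_amplitude,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synth_config")
}

# Smooth low-frequency surface in [0, 1]: coarse uniform grid, bilinear
# upsampling. Cell size ties the correlation length to the outer-window
# scale of the scatter stage, so regional estimates see smooth fields.
smooth_surface <- function(height, width, cell = 64) {
  nrc <- max(2L, ceiling(height / cell) + 1L)
  ncc <- max(2L, ceiling(width / cell) + 1L)
  coarse <- matrix(stats::runif(nrc * ncc), nrc, ncc)
  rg <- seq(1, nrc, length.out = height)
  cg <- seq(1, ncc, length.out = width)
  r0 <- pmin(floor(rg), nrc - 1L); fr <- rg - r0
  c0 <- pmin(floor(cg), ncc - 1L); fc <- cg - c0
  a <- coarse[r0, c0, drop = FALSE]; b <- coarse[r0, c0 + 1L, drop = FALSE]
  d <- coarse[r0 + 1L, c0, drop = FALSE]; e <- coarse[r0 + 1L, c0 + 1L, drop = FALSE]
  wr <- matrix(fr, height, width); wc <- matrix(fc, height, width, byrow = TRUE)
  s <- a * (1 - wr) * (1 - wc) + b * (1 - wr) * wc +
    d * wr * (1 - wc) + e * wr * wc
  lo <- min(s); hi <- max(s)
  if (hi == lo) matrix(0.5, height, width) else (s - lo) / (hi - lo)
}

# Draw one smooth stroke: a wandering centreline crossing the image
# left-to-right with tapering width. Returns a logical support mask.
draw_stroke <- function(height, width, width_range) {
  steps <- stats::rnorm(width, 0, 0.6)
  drift <- stats::runif(1, -0.3, 0.3)
  path <- cumsum(stats::filter(c(steps + drift), rep(1 / 9, 9),
                               circular = TRUE))
  rows <- stats::runif(1, 0.1, 0.9) * height + path - mean(path)
  base_w <- stats::runif(1, width_range[1], width_range[2])
  taper <- 0.75 + 0.5 * smooth_surface(1, width, cell = 48)[1, ]
  half <- pmax(base_w * taper, 1) / 2
  mask <- matrix(FALSE, height, width)
  for (j in seq_len(width)) {
    lo <- max(1L, ceiling(rows[j] - half[j]))
    hi <- min(height, floor(rows[j] + half[j]))
    if (lo <= hi) mask[lo:hi, j] <- TRUE
  }
  mask
}

#' Generate a clean vessel phantom and its ground-truth mask
#'
#' Builds a smooth bright background (gray about 180 to 220) and subtracts
#' Gaussian-smoothed curvilinear strokes, so vessel borders change with a
#' continuous gray gradient. Fully deterministic per seed.
#'
#' @param config A [synth_config()].
#' @return List with `clean` (8-bit matrix) and `vein_mask` (logical matrix,
#'   `TRUE` on the stroke support).
#' @export
generate_vein_pattern <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    h <- config$height; w <- config$width
    background <- 195 + 30 * (smooth_surface(h, w, cell = 96) - 0.5)
    nv <- if (config$n_vessels[1] == config$n_vessels[2]) config$n_vessels[1]
    else sample(config$n_vessels[1]:config$n_vessels[2], 1)
    mask <- matrix(FALSE, h, w)
    depth_field <- matrix(0, h, w)
    if (nv > 0) for (v in seq_len(nv)) {
      stroke <- draw_stroke(h, w, config$vessel_width)
      depth <- stats::runif(1, config$vein_depth[1], config$vein_depth[2])
      depth_field <- pmax(depth_field, depth * as.numeric(stroke))
      mask <- mask | stroke
    }
    depth_field <- gaussian_blur(depth_field / 255,
                                 gray_quant_config(sigma = 1, kernel_radius = 3)) * 255
    clean <- round(clamp(background - depth_field, 0, 255))
    list(clean = clean, vein_mask = mask)
  })
}

#' Generate the forward degradation fields
#'
#' Builds smooth low-frequency surfaces for the absorption rate (mapped into
#' `eps_range`) and the incident illumination
#' `255 * (1 + illum_amplitude * surface)` with `surface` in `[-1, 1]`,
#' clipped into `(0, 255]`.
#'
#' @param config A [synth_config()].
#' @return List with `eps_field` and `illum_field` matrices.
#' @export
make_degradation_fields <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed + 500000L, {
    h <- config$height; w <- config$width
    s_eps <- smooth_surface(h, w)
    s_illum <- 2 * smooth_surface(h, w) - 1
    eps_field <- config$eps_range[1] +
      s_eps * (config$eps_range[2] - config$eps_range[1])
    illum_field <- clamp(255 * (1 + config$illum_amplitude * s_illum), 1, 255)
    list(eps_field = eps_field, illum_field = illum_field)
  })
}

#' Apply the forward scattering degradation
#'
#' `I = clean * eps + illum * (1 - eps) + noise`, clipped to `[0, 255]` and
#' rounded to 8-bit. With `eps` identically 1 and zero noise the output is
#' the clean image unchanged.
#'
#' @param clean Clean 8-bit image matrix.
#' @param eps_field Absorption field in `(0, 1]`.
#' @param illum_field Illumination field in `(0, 255]`.
#' @param config A [synth_config()]; supplies `noise_sigma` and the seed for
#'   the noise draw.
#' @return Degraded 8-bit image matrix.
#' @export
apply_degradation <- function(clean, eps_field, illum_field,
                              config = synth_config()) {
  check_image(clean, "clean")
  check_same_shape(clean, eps_field, "clean", "eps_field")
  check_same_shape(clean, illum_field, "clean", "illum_field")
  mixed <- clean * eps_field + illum_field * (1 - eps_field)
  if (config$noise_sigma > 0)
    mixed <- mixed + with_seed(config$seed + 900000L,
                               matrix(stats::rnorm(length(clean), 0, config$noise_sigma),
                                      nrow(clean), ncol(clean)))
  round(clamp(mixed, 0, 255))
}

#' Generate one complete synthetic sample
#'
#' @param config A [synth_config()].
#' @return An object of class `synthetic_sample`: list with `clean`,
#'   `degraded`, `vein_mask`, `eps_field`, `illum_field` and `seed`.
#' @export
synth_sample <- function(config = synth_config()) {
  pat <- generate_vein_pattern(config)
  fields <- make_degradation_fields(config)
  degraded <- apply_degradation(pat$clean, fields$eps_field,
                                fields$illum_field, config)
  structure(list(clean = pat$clean, degraded = degraded,
                 vein_mask = pat$vein_mask, eps_field = fields$eps_field,
                 illum_field = fields$illum_field, seed = config$seed,
                 severity = config$severity),
            class = "synthetic_sample")
}

#' Generate and write a dataset of synthetic samples
#'
#' Produces `n` samples with seeds `config$seed, config$seed + 1, ...` and
#' writes them to `dir` as 8-bit grayscale PNGs (`clean_NNNN.png`,
#' `degraded_NNNN.png`, binary `mask_NNNN.png`) plus a tab-separated
#' `manifest.tsv` recording the per-sample parameters. Regeneration with the
#' same configuration yields bit-identical files.
#'
#' @param config A [synth_config()]; its `seed` is the first sample's seed.
#' @param n Number of samples, at least 1.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the list of `synthetic_sample` objects.
#' @export
generate_dataset <- function(config = synth_config(), n, dir) {
  stopifnot(inherits(config, "synth_config"))
  if (n < 1) stopf("'n' must be at least 1")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory '%s'", dir)
  samples <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    s <- synth_sample(cfg)
    tag <- sprintf("%04d", i - 1L)
    write_gray_image(s$clean, file.path(dir, paste0("clean_", tag, ".png")))
    write_gray_image(s$degraded, file.path(dir, paste0("degraded_", tag, ".png")))
    write_gray_image(ifelse(s$vein_mask, 255, 0),
                     file.path(dir, paste0("mask_", tag, ".png")))
    rows[[i]] <- data.frame(index = i - 1L, seed = cfg$seed,
                            severity = cfg$severity,
                            height = cfg$height, width = cfg$width,
                            eps_lo = cfg$eps_range[1], eps_hi = cfg$eps_range[2],
                            illum_amplitude = cfg$illum_amplitude,
                            noise_sigma = cfg$noise_sigma)
    samples[[i]] <- s
  }
  utils::write.table(do.call(rbind, rows), file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(samples)
}
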