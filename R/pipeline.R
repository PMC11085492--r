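#' Full pipeline configuration
#'
#' Bundles the per-stage configurations. Defaults reproduce the standard
#' parameterization: sigma 1.5 for the Stage-1 blur, top 5 percent regional
#' light, cutoff 25 with gains 2 / 0.5 for the homomorphic filter.
#'
#' @param gray A [gray_quant_config()].
#' @param scatter A [scatter_config()].
#' @param homomorphic A [homomorphic_config()].
#' @param metrics A [metrics_config()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(gray = gray_quant_config(),
                            scatter = scatter_config(),
                            homomorphic = homomorphic_config(),
                            metrics = metrics_config()) {
  stopifnot(inherits(gray, "gray_quant_config"),
            inherits(scatter, "scatter_config"),
            inherits(homomorphic, "homomorphic_config"),
            inherits(metrics, "metrics_config"))
  structure(list(gray = gray, scatter = scatter, homomorphic = homomorphic,
                 metrics = metrics),
            class = "pipeline_config")
}

stage_stats <- function(x) {
  c(min = min(x), max = max(x), mean = mean(x))
}

#' Enhance a degraded vessel image end-to-end
#'
#' Runs the three stages in order: gray-level quantization
#' ([quantize_gray()]), scattering-model restoration ([restore_scatter()])
#' and homomorphic normalization ([homomorphic_normalize()]). The
#' enhancement path contains no randomness: identical input and
#' configuration give bit-identical output.
#'
#' @param image Numeric matrix of 8-bit gray values with at least two
#'   distinct levels.
#' @param config A [pipeline_config()].
#' @param skip_stages Character vector of stages to bypass for ablation-style
#'   runs; any of `"quantize"`, `"scatter"`, `"homomorphic"`.
#' @param keep_intermediates If `TRUE`, the per-stage images are returned in
#'   the report.
#' @return List with `image` (final 8-bit matrix) and `report` (per-stage
#'   min/max/mean statistics, the exponent `r` used, skipped stages, and the
#'   intermediates when requested).
#' @export
enhance <- function(image, config = pipeline_config(),
                    skip_stages = character(), keep_intermediates = FALSE) {
  check_image(image)
  stopifnot(inherits(config, "pipeline_config"))
  bad <- setdiff(skip_stages, c("quantize", "scatter", "homomorphic"))
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  run_stage <- function(name, fun, x) {
    tryCatch(fun(x), error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  stats <- list(input = stage_stats(image))
  inter <- list()
  cur <- image
  r_used <- NA_real_
  if (!"quantize" %in% skip_stages) {
    cur <- run_stage("quantize", function(x) quantize_gray(x, config$gray), cur)
    r_used <- attr(cur, "r")
    attr(cur, "r") <- NULL
    stats$quantize <- stage_stats(cur)
    if (keep_intermediates) inter$quantize <- cur
  }
  if (!"scatter" %in% skip_stages) {
    cur <- run_stage("scatter", function(x) restore_scatter(x, config$scatter), cur)
    stats$scatter <- stage_stats(cur)
    if (keep_intermediates) inter$scatter <- cur
  }
  if (!"homomorphic" %in% skip_stages) {
    cur <- run_stage("homomorphic",
                     function(x) homomorphic_normalize(x, config$homomorphic), cur)
    stats$homomorphic <- stage_stats(cur)
  }
  report <- list(stage_stats = stats, r = r_used, skipped = skip_stages)
  if (keep_intermediates) report$intermediates <- inter
  list(image = cur, report = report)
}

#' Read an 8-bit grayscale image
#'
#' Supports PNG and TIFF. Multi-channel files are accepted only when all
#' channels carry identical gray values (common for transmission images
#' stored as RGB) and are collapsed to a single channel; an alpha channel
#' must be fully opaque and is dropped.
#'
#' @param path File path; format chosen by extension.
#' @return Numeric matrix of integer gray values in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stopf("unsupported image format '.%s' for '%s' (use PNG or TIFF)",
                      ext, path))
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    if (nch == 4L || nch == 2L) {
      alpha <- arr[, , nch]
      if (any(alpha != 1))
        stopf("'%s' has a non-opaque alpha channel", path)
      arr <- arr[, , -nch, drop = FALSE]
      nch <- dim(arr)[3]
    }
    first <- arr[, , 1]
    for (k in seq_len(nch)[-1])
      if (any(arr[, , k] != first))
        stopf("'%s' is a color image with differing channels; cannot collapse to grayscale",
              path)
    arr <- first
  }
  round(arr * 255)
}

#' Write an 8-bit grayscale image
#'
#' Values are rounded and clipped into `[0, 255]`. Writing then reading the
#' same matrix is a lossless roundtrip.
#'
#' @param image Numeric matrix of gray values in `[0, 255]`.
#' @param path Output path; `.png`, `.tif` or `.tiff`.
#' @return Invisibly, `path`.
#' @export
write_gray_image <- function(image, path) {
  check_image(image)
  unit <- round(clamp(image, 0, 255)) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(unit, path),
         tif = , tiff = tiff::writeTIFF(unit, path, bits.per.sample = 8L),
         stopf("unsupported output format '.%s' for '%s' (use PNG or TIFF)",
               ext, path))
  invisible(path)
}

#' Write a float field as 32-bit TIFF
#'
#' Exports intermediate fields (pixel-mutation filter output, light,
#' absorption, restored image) for inspection. Float TIFF samples live on
#' the unit scale, so values are divided by `scale` before writing;
#' absorption maps need `scale = 1`, gray-valued fields `scale = 255`.
#'
#' @param field Numeric matrix with values in `[0, scale]`.
#' @param path Output path ending in `.tif` or `.tiff`.
#' @param scale Divisor mapping the field into `[0, 1]`; default 1.
#' @return Invisibly, `path`.
#' @export
write_float_tiff <- function(field, path, scale = 1) {
  check_image(field, "field")
  if (min(field) < 0 || max(field) > scale)
    stopf("field values in [%g, %g] exceed [0, scale = %g]; pick a scale covering the field",
          min(field), max(field), scale)
  tiff::writeTIFF(field / scale, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

# Known configuration keys, namespaced by stage.
config_key_table <- function() {
  list(gray = c("r", "Gm", "Gn", "sigma", "kernel_radius"),
       scatter = c("omega1", "omega2", "top_fraction", "eps_min"),
       homomorphic = c("D0", "rH", "rL", "c", "order", "log_offset"),
       metrics = c("ssim_block", "ssim_c1", "ssim_c2", "cii_block"))
}

#' Load a pipeline configuration from a YAML file
#'
#' Accepts flat namespaced keys (`gray.sigma: 1.2`) or nested blocks
#' (`gray:` / `  sigma: 1.2`). Absent keys take their defaults; unknown keys
#' and invariant violations raise errors naming the key.
#'
#' @param path Path to a YAML file, or `NULL` for the full default set.
#' @return A [pipeline_config()].
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(pipeline_config())
  if (!file.exists(path)) stopf("config file '%s' not found", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  flat <- list()
  for (key in names(raw)) {
    val <- raw[[key]]
    if (is.list(val)) {
      for (sub in names(val)) flat[[paste0(key, ".", sub)]] <- val[[sub]]
    } else flat[[key]] <- val
  }
  known <- config_key_table()
  args <- list(gray = list(), scatter = list(), homomorphic = list(),
               metrics = list())
  for (key in names(flat)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !parts[1] %in% names(known) ||
        !parts[2] %in% known[[parts[1]]])
      stopf("unknown config key '%s'", key)
    args[[parts[1]]][[parts[2]]] <- flat[[key]]
  }
  pipeline_config(gray = do.call(gray_quant_config, args$gray),
                  scatter = do.call(scatter_config, args$scatter),
                  homomorphic = do.call(homomorphic_config, args$homomorphic),
                  metrics = do.call(metrics_config, args$metrics))
}
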