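#' Configuration for the evaluation metrics
#'
#' @param ssim_block Side length of the non-overlapping local regions used by
#'   [mssim()]; default 8.
#' @param ssim_c1,ssim_c2 Stabilizing constants of the structural-similarity
#'   formula; defaults `(0.01 * 255)^2` and `(0.03 * 255)^2`, the standard
#'   choices for 8-bit dynamic range.
#' @param cii_block Side length of the local regions used by [cii()];
#'   default 8.
#' @return An object of class `metrics_config`.
#' @export
metrics_config <- function(ssim_block = 8, ssim_c1 = (0.01 * 255)^2,
                           ssim_c2 = (0.03 * 255)^2, cii_block = 8) {
  if (ssim_block < 2 || cii_block < 2) stopf("block sizes must be at least 2")
  if (ssim_c1 <= 0 || ssim_c2 <= 0) stopf("stabilizers must be positive")
  structure(list(ssim_block = as.integer(ssim_block), ssim_c1 = ssim_c1,
                 ssim_c2 = ssim_c2, cii_block = as.integer(cii_block)),
            class = "metrics_config")
}

#' Structural similarity of one region pair
#'
#' Computes `(2 mx my + c1)(2 sxy + c2) / ((mx^2 + my^2 + c1)(sx + sy + c2))`
#' with `mx, my` the block means, `sx, sy` the block variances and `sxy` the
#' covariance (population moments, i.e. divided by the pixel count).
#' Symmetric in its arguments; identical blocks score exactly 1.
#'
#' @param x,y Numeric matrices of equal shape (one local region each).
#' @param config A [metrics_config()].
#' @return Similarity score in `[-1, 1]`.
#' @export
ssim_region <- function(x, y, config = metrics_config()) {
  check_image(x, "x"); check_image(y, "y")
  check_same_shape(x, y)
  stopifnot(inherits(config, "metrics_config"))
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  (2 * mx * my + config$ssim_c1) * (2 * cxy + config$ssim_c2) /
    ((mx^2 + my^2 + config$ssim_c1) * (vx + vy + config$ssim_c2))
}

# Top-left corners of the non-overlapping b x b tiles covering a matrix;
# partial edge tiles are dropped.
tile_corners <- function(nr, nc, b) {
  rows <- seq.int(1L, nr - b + 1L, by = b)
  cols <- seq.int(1L, nc - b + 1L, by = b)
  expand.grid(row = rows, col = cols)
}

#' Mean structural similarity (MSSIM)
#'
#' Mean of [ssim_region()] over the non-overlapping square blocks tiling the
#' two images (partial edge blocks dropped). `mssim(x, x)` is exactly 1; a
#' value below 1 measures how far the second image departs from the first.
#'
#' @param x,y Numeric matrices of equal shape, at least one block in size.
#' @param config A [metrics_config()].
#' @return Mean similarity score in `[-1, 1]`.
#' @export
mssim <- function(x, y, config = metrics_config()) {
  check_image(x, "x"); check_image(y, "y")
  check_same_shape(x, y)
  stopifnot(inherits(config, "metrics_config"))
  b <- config$ssim_block
  if (nrow(x) < b || ncol(x) < b)
    stopf("images (%dx%d) are smaller than one %dx%d block",
          nrow(x), ncol(x), b, b)
  tiles <- tile_corners(nrow(x), ncol(x), b)
  scores <- mapply(function(i, j) {
    ssim_region(x[i:(i + b - 1L), j:(j + b - 1L)],
                y[i:(i + b - 1L), j:(j + b - 1L)], config)
  }, tiles$row, tiles$col)
  mean(scores)
}

# Mean blockwise Michelson contrast (Qmax - Qmin) / (Qmax + Qmin);
# a block with Qmax + Qmin == 0 contributes 0.
block_contrast <- function(x, b) {
  tiles <- tile_corners(nrow(x), ncol(x), b)
  vals <- mapply(function(i, j) {
    blk <- x[i:(i + b - 1L), j:(j + b - 1L)]
    hi <- max(blk); lo <- min(blk)
    if (hi + lo == 0) 0 else (hi - lo) / (hi + lo)
  }, tiles$row, tiles$col)
  mean(vals)
}

#' Contrast improvement index (CII)
#'
#' Ratio of the mean blockwise Michelson contrast of the processed image to
#' that of the raw image, over non-overlapping square tiles (partial edge
#' tiles dropped). `cii(x, x)` is exactly 1 for any non-constant image;
#' values above 1 indicate a contrast gain.
#'
#' @param raw,processed Numeric matrices of equal shape.
#' @param config A [metrics_config()].
#' @return Non-negative contrast ratio.
#' @export
cii <- function(raw, processed, config = metrics_config()) {
  check_image(raw, "raw"); check_image(processed, "processed")
  check_same_shape(raw, processed, "raw", "processed")
  stopifnot(inherits(config, "metrics_config"))
  b <- config$cii_block
  if (nrow(raw) < b || ncol(raw) < b)
    stopf("images (%dx%d) are smaller than one %dx%d block",
          nrow(raw), ncol(raw), b, b)
  c_raw <- block_contrast(raw, b)
  if (c_raw == 0)
    stopf("degenerate input: raw image has zero blockwise contrast")
  block_contrast(processed, b) / c_raw
}

#' Detection error tradeoff (DET) curve and equal error rate
#'
#' Sweeps a decision threshold over the union of the observed similarity
#' scores. At threshold `t`, the false accept rate is the fraction of
#' impostor scores `>= t` and the false reject rate the fraction of genuine
#' scores `< t`. The equal error rate is taken where the two rates cross,
#' with linear interpolation between the bracketing thresholds. Scores are
#' similarities (higher means more likely genuine); negate distances before
#' calling.
#'
#' @param genuine Numeric vector of genuine-comparison scores.
#' @param impostor Numeric vector of impostor-comparison scores.
#' @return An object of class `det_result`: list with `thresholds` (ascending),
#'   `far`, `frr` (per-threshold rates in `[0, 1]`) and `eer` (scalar).
#' @export
det_curve <- function(genuine, impostor) {
  if (length(genuine) == 0L || length(impostor) == 0L)
    stopf("both score lists must be non-empty")
  if (any(!is.finite(genuine)) || any(!is.finite(impostor)))
    stopf("scores must be finite")
  thr <- sort(unique(c(genuine, impostor)))
  far <- vapply(thr, function(t) mean(impostor >= t), numeric(1))
  frr <- vapply(thr, function(t) mean(genuine < t), numeric(1))
  d <- far - frr  # non-increasing in the threshold
  if (all(d >= 0)) {
    eer <- (far[length(far)] + frr[length(frr)]) / 2
  } else if (all(d <= 0)) {
    eer <- (far[1L] + frr[1L]) / 2
  } else {
    k <- which(d <= 0)[1L]  # first crossing
    if (d[k] == 0) {
      eer <- far[k]
    } else {
      w <- d[k - 1L] / (d[k - 1L] - d[k])
      eer <- (1 - w) * far[k - 1L] + w * far[k]
    }
  }
  structure(list(thresholds = thr, far = far, frr = frr, eer = eer),
            class = "det_result")
}

#' @export
print.det_result <- function(x, ...) {
  cat(sprintf("DET curve over %d thresholds; EER = %.4f\n",
              length(x$thresholds), x$eer))
  invisible(x)
}
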