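#' @useDynLib veinclear, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Internal helpers shared by the pipeline stages. Images are plain numeric
# matrices indexed (row, col) with the origin at the top-left.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_image <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("%s must be a numeric matrix", what)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stopf("%s must have at least one row and one column", what)
  if (any(!is.finite(x)))
    stopf("%s contains non-finite values", what)
  invisible(x)
}

check_same_shape <- function(x, y, what_x = "x", what_y = "y") {
  if (!identical(dim(x), dim(y)))
    stopf("%s (%dx%d) and %s (%dx%d) must have identical dimensions",
          what_x, nrow(x), ncol(x), what_y, nrow(y), ncol(y))
  invisible(NULL)
}

check_odd_window <- function(w, name) {
  if (length(w) != 1L || !is.finite(w) || w < 3L || w %% 2L != 1L)
    stopf("'%s' must be a single odd integer >= 3, got %s", name,
          paste(w, collapse = ","))
  invisible(as.integer(w))
}

# Reflected index vector for padding: border pixel repeated
# (d c b a | a b c d | d c b a), matching the compiled filters.
reflect_indices <- function(n, r) {
  idx <- seq.int(1L - r, n + r)
  if (n == 1L) return(rep(1L, length(idx)))
  while (any(idx < 1L | idx > n)) {
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
  }
  idx
}

# Reflect-pad a matrix by r pixels on every side.
pad_reflect <- function(x, r) {
  x[reflect_indices(nrow(x), r), reflect_indices(ncol(x), r), drop = FALSE]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
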