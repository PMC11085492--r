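# Independent brute-force oracles. Everything here is written from the
# operation definitions directly -- nested loops, explicit sorts, naive DFT
# -- and never calls the package's computational path.

# Reflected padding built explicitly: border pixel repeated
# (d c b a | a b c d | d c b a).
oracle_pad <- function(x, r) {
  n <- nrow(x); m <- ncol(x)
  ref <- function(i, n) {
    while (i < 1L || i > n) {
      if (i < 1L) i <- 1L - i
      if (i > n) i <- 2L * n + 1L - i
    }
    i
  }
  out <- matrix(0, n + 2 * r, m + 2 * r)
  for (i in seq_len(n + 2 * r))
    for (j in seq_len(m + 2 * r))
      out[i, j] <- x[ref(i - r, n), ref(j - r, m)]
  out
}

# Direct nested-loop convolution with a (2r+1)^2 kernel, reflect padding.
oracle_convolve <- function(x, kernel) {
  r <- (nrow(kernel) - 1L) %/% 2L
  p <- oracle_pad(x, r)
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x)))
    for (j in seq_len(ncol(x)))
      out[i, j] <- sum(p[i:(i + 2 * r), j:(j + 2 * r)] * kernel)
  out
}

# Truncated isotropic Gaussian kernel, renormalized to unit sum.
oracle_gaussian_kernel <- function(sigma, radius) {
  u <- seq.int(-radius, radius)
  k <- outer(u, u, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  k / sum(k)
}

# Exhaustive pixel-mutation filter: every window gathered explicitly.
oracle_fmp <- function(x, w1, w2) {
  r1 <- (w1 - 1L) %/% 2L; r2 <- (w2 - 1L) %/% 2L
  p <- oracle_pad(x, r1)
  out <- matrix(0, nrow(x), ncol(x))
  ratio <- (w2 * w2) / (w1 * w1)
  for (i in seq_len(nrow(x)))
    for (j in seq_len(ncol(x))) {
      win1 <- p[(i + r1 - r1):(i + r1 + r1), (j + r1 - r1):(j + r1 + r1)]
      win2 <- p[(i + r1 - r2):(i + r1 + r2), (j + r1 - r2):(j + r1 + r2)]
      mx1 <- max(win1); mx2 <- max(win2)
      C <- sum(win1 <= x[i, j]) / (w1 * w1)
      N <- if (C >= ratio) 1 else -1
      out[i, j] <- max(0, mx2 + N * min(C * (mx1 - mx2), mx1))
    }
  out
}

# Per-window full sort, mean of the top ceil(frac * count) values.
oracle_topfrac_mean <- function(x, w, frac) {
  r <- (w - 1L) %/% 2L
  p <- oracle_pad(x, r)
  k <- max(1L, ceiling(frac * w * w))
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x)))
    for (j in seq_len(ncol(x))) {
      win <- sort(as.numeric(p[i:(i + 2 * r), j:(j + 2 * r)]),
                  decreasing = TRUE)
      out[i, j] <- mean(win[seq_len(k)])
    }
  out
}

# Scalar structural similarity from its definition.
oracle_ssim <- function(x, y, c1, c2) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- sum((x - mx)^2) / n; vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

# Blockwise MSSIM: explicit loop over full non-overlapping tiles.
oracle_mssim <- function(x, y, b, c1, c2) {
  vals <- c()
  for (i in seq(1L, nrow(x) - b + 1L, by = b))
    for (j in seq(1L, ncol(x) - b + 1L, by = b))
      vals <- c(vals, oracle_ssim(x[i:(i + b - 1L), j:(j + b - 1L)],
                                  y[i:(i + b - 1L), j:(j + b - 1L)], c1, c2))
  mean(vals)
}

oracle_block_contrast <- function(x, b) {
  vals <- c()
  for (i in seq(1L, nrow(x) - b + 1L, by = b))
    for (j in seq(1L, ncol(x) - b + 1L, by = b)) {
      blk <- x[i:(i + b - 1L), j:(j + b - 1L)]
      s <- max(blk) + min(blk)
      vals <- c(vals, if (s == 0) 0 else (max(blk) - min(blk)) / s)
    }
  mean(vals)
}

oracle_cii <- function(raw, processed, b) {
  oracle_block_contrast(processed, b) / oracle_block_contrast(raw, b)
}

# Exhaustive threshold sweep for the DET curve; the EER is located by
# scanning |FAR - FRR| and linearly interpolating the sign change.
oracle_det <- function(genuine, impostor) {
  thr <- sort(unique(c(genuine, impostor)))
  far <- sapply(thr, function(t) sum(impostor >= t) / length(impostor))
  frr <- sapply(thr, function(t) sum(genuine < t) / length(genuine))
  d <- far - frr
  sgn <- which(d <= 0)
  if (length(sgn) == 0L) {
    eer <- (far[length(d)] + frr[length(d)]) / 2
  } else {
    k <- sgn[1L]
    if (k == 1L || d[k] == 0) {
      eer <- if (d[k] == 0) far[k] else (far[1L] + frr[1L]) / 2
    } else {
      w <- d[k - 1L] / (d[k - 1L] - d[k])
      eer <- (1 - w) * far[k - 1L] + w * far[k]
    }
  }
  list(thresholds = thr, far = far, frr = frr, eer = eer)
}

# Naive centred-spectrum homomorphic pipeline built on explicit DFT
# matrices W[j, k] = exp(-2*pi*i*j*k/n): spectrum shifted to the centre,
# multiplied by a transfer function rebuilt from its formula, shifted back,
# inverse transformed.
oracle_homomorphic <- function(img, D0, rH, rL, cc, n_order, offset) {
  nr <- nrow(img); nc <- ncol(img)
  dftmat <- function(n) {
    jk <- outer(0:(n - 1), 0:(n - 1))
    exp(-2i * pi * jk / n)
  }
  Wr <- dftmat(nr); Wc <- dftmat(nc)
  # forward shift: zero frequency (index 1) moves to floor(n/2) + 1
  shift1 <- function(n) ((seq_len(n) - 1 - floor(n / 2)) %% n) + 1
  lg <- log(img + offset)
  Fu <- Wr %*% lg %*% Wc
  Fc <- Fu[shift1(nr), shift1(nc)]             # zero frequency to centre
  u0 <- floor(nr / 2); v0 <- floor(nc / 2)
  D2 <- outer((0:(nr - 1) - u0)^2, (0:(nc - 1) - v0)^2, "+")
  H <- (rH - rL) * (1 - exp(-cc * (D2 / D0^2)^n_order)) + rL
  Fc <- Fc * H
  Fu <- Fc[order(shift1(nr)), order(shift1(nc))]  # inverse permutation
  flt <- Re(Conj(Wr) %*% Fu %*% Conj(Wc)) / (nr * nc)
  out <- exp(flt) - offset
  lo <- min(out); hi <- max(out)
  round((out - lo) / (hi - lo) * 255)
}

# Rank-based area under the ROC of a score against a binary mask.
mask_auc <- function(img, mask, invert = TRUE) {
  sc <- as.numeric(img) * (if (invert) -1 else 1)
  y <- as.numeric(mask)
  r <- rank(sc)
  n1 <- sum(y); n0 <- sum(1 - y)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

random_image <- function(nr, nc, lo = 0, hi = 255) {
  matrix(sample(lo:hi, nr * nc, replace = TRUE), nr, nc)
}
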