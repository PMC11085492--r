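small_cfg <- function() scatter_config(omega1 = 5, omega2 = 3)

test_that("pixel-mutation filter is identity on constant images", {
  x <- matrix(77, 12, 15)
  expect_equal(fmp_filter(x, small_cfg()), x)
})

test_that("pixel-mutation filter keeps an isolated bright pixel at its value", {
  x <- matrix(40, 11, 11)
  x[6, 6] <- 200
  got <- fmp_filter(x, small_cfg())
  # at the bright pixel mx1 = mx2 = 200, C = 1, so FMP = 200 + min(0, 200)
  expect_equal(got[6, 6], 200)
})

test_that("pixel-mutation filter matches the exhaustive window oracle", {
  set.seed(61)
  x <- random_image(9, 9)
  expect_equal(fmp_filter(x, small_cfg()), oracle_fmp(x, 5, 3),
               tolerance = 1e-12)
  for (i in 1:10) {
    nr <- sample(7:20, 1); nc <- sample(7:20, 1)
    x <- random_image(nr, nc)
    cfg <- if (i %% 2) small_cfg() else scatter_config(omega1 = 7, omega2 = 3)
    expect_equal(fmp_filter(x, cfg), oracle_fmp(x, cfg$omega1, cfg$omega2),
                 tolerance = 1e-12)
  }
})

test_that("regional light intensity matches the sort oracle and order-statistic bounds", {
  x <- matrix(88, 7, 7)
  expect_equal(regional_light_intensity(x, small_cfg()), x)

  # a full window holding 1..25 with 5% rule: top ceil(1.25) = 2 values
  y <- matrix(1:25, 5, 5)
  got <- regional_light_intensity(y, small_cfg())
  expect_equal(got[3, 3], mean(c(25, 24)))

  set.seed(71)
  for (i in 1:8) {
    x <- random_image(16, 16)
    cfg <- scatter_config(omega1 = sample(c(5, 7, 9), 1), omega2 = 3)
    A <- regional_light_intensity(x, cfg)
    expect_equal(A, oracle_topfrac_mean(x, cfg$omega1, 0.05),
                 tolerance = 1e-12)
    # dominance: windowed mean <= A <= windowed max
    r <- (cfg$omega1 - 1) / 2
    p <- oracle_pad(x, r)
    for (pt in list(c(1, 1), c(8, 9), c(16, 16))) {
      win <- p[pt[1]:(pt[1] + 2 * r), pt[2]:(pt[2] + 2 * r)]
      expect_gte(A[pt[1], pt[2]], mean(win))
      expect_lte(A[pt[1], pt[2]], max(win))
    }
  }
})

test_that("absorption map is the clamped ratio of filter output to light", {
  cfg <- scatter_config()
  A <- matrix(100, 4, 4)
  expect_equal(absorption_map(matrix(50, 4, 4), A, cfg), matrix(0.5, 4, 4))
  expect_equal(absorption_map(A, A, cfg), matrix(1, 4, 4))
  expect_equal(absorption_map(2 * A, A, cfg), matrix(1, 4, 4))
  expect_equal(absorption_map(matrix(1, 4, 4), A, cfg), matrix(0.1, 4, 4))
  expect_error(absorption_map(A, matrix(0, 4, 4), cfg), "positive")
})

test_that("scattering inversion is the exact algebraic inverse when unclamped", {
  expect_equal(invert_scattering(matrix(120, 1, 1), matrix(200, 1, 1),
                                 matrix(0.5, 1, 1)),
               matrix(40, 1, 1))
  # eps = 1 degenerates to the identity
  set.seed(81)
  I <- random_image(10, 10)
  expect_equal(invert_scattering(I, matrix(150, 10, 10), matrix(1, 10, 10)), I)

  for (i in 1:20) {
    J <- matrix(runif(36, 0, 255), 6, 6)
    A <- matrix(runif(36, 50, 255), 6, 6)
    eps <- matrix(runif(36, 0.1, 1), 6, 6)
    forward <- J * eps + A * (1 - eps)
    expect_equal(invert_scattering(forward, A, eps), J, tolerance = 1e-9)
  }
  expect_error(invert_scattering(matrix(1, 2, 2), matrix(1, 3, 3),
                                 matrix(1, 2, 2)), "dimensions")
})

test_that("restore composes its parts, fixes constants, and bounds its output", {
  x <- matrix(120, 20, 20)
  cfg <- small_cfg()
  expect_equal(restore_scatter(x, cfg), x)

  set.seed(91)
  y <- random_image(20, 24, lo = 30, hi = 230)
  fmp <- fmp_filter(y, cfg)
  A <- regional_light_intensity(y, cfg)
  eps <- absorption_map(fmp, A, cfg)
  expect_equal(restore_scatter(y, cfg), invert_scattering(y, A, eps))
  expect_true(all(eps >= 0.1 & eps <= 1))
  out <- restore_scatter(y, cfg)
  expect_true(all(out >= 0 & out <= 255))
})

test_that("restoration expands blockwise Michelson contrast on a severe phantom", {
  s <- synth_sample(synth_config(severity = "severe", seed = 0))
  q <- quantize_gray(s$degraded)
  r <- restore_scatter(q)
  b <- 8
  n_mixed <- 0; n_expanded <- 0
  for (i in seq(1, nrow(q) - b + 1, b))
    for (j in seq(1, ncol(q) - b + 1, b)) {
      m <- s$vein_mask[i:(i + b - 1), j:(j + b - 1)]
      if (any(m) && !all(m)) {
        n_mixed <- n_mixed + 1
        qb <- q[i:(i + b - 1), j:(j + b - 1)]
        rb <- r[i:(i + b - 1), j:(j + b - 1)]
        mc <- function(z) (max(z) - min(z)) / (max(z) + min(z))
        if (mc(rb) > mc(qb)) n_expanded <- n_expanded + 1
      }
    }
  expect_gt(n_mixed, 50)
  expect_gte(n_expanded / n_mixed, 0.95)
})

test_that("invalid scatter configurations are rejected", {
  expect_error(scatter_config(omega1 = 7, omega2 = 7), "smaller")
  expect_error(scatter_config(omega1 = 8), "odd")
  expect_error(scatter_config(omega2 = 1), "odd")
  expect_error(scatter_config(top_fraction = 0), "top_fraction")
  expect_error(scatter_config(eps_min = 1), "eps_min")
})
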