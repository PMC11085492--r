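test_that("phantom generation is bit-identical per seed and leaves the RNG alone", {
  cfg <- synth_config(seed = 7, height = 64, width = 96)
  a <- generate_vein_pattern(cfg)
  set.seed(999)          # generator must not depend on ambient RNG state
  before <- .Random.seed
  b <- generate_vein_pattern(cfg)
  expect_identical(before, .Random.seed)
  expect_identical(a$clean, b$clean)
  expect_identical(a$vein_mask, b$vein_mask)

  s1 <- synth_sample(cfg)
  s2 <- synth_sample(cfg)
  expect_identical(s1$degraded, s2$degraded)
  expect_identical(s1$eps_field, s2$eps_field)
})

test_that("clean phantoms have dark vessels on a bright background", {
  # mask-area bounds are calibrated for the default 240x320 frame
  n_checked <- 0
  for (seed in 0:99) {
    cfg <- synth_config(seed = seed)
    p <- generate_vein_pattern(cfg)
    expect_true(all(p$clean >= 0 & p$clean <= 255))
    frac <- mean(p$vein_mask)
    expect_gte(frac, 0.02)
    expect_lte(frac, 0.35)
    gap <- mean(p$clean[!p$vein_mask]) - mean(p$clean[p$vein_mask])
    expect_gte(gap, cfg$vein_depth[1] / 2)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 100)
})

test_that("zero vessels yields a valid image with an empty mask", {
  p <- generate_vein_pattern(synth_config(seed = 3, n_vessels = c(0, 0),
                                          height = 64, width = 64))
  expect_false(any(p$vein_mask))
  expect_true(all(p$clean >= 0 & p$clean <= 255))
})

test_that("degradation fields respect their configured ranges and degenerate limits", {
  cfg0 <- synth_config(seed = 5, illum_amplitude = 0, height = 64, width = 64)
  f0 <- make_degradation_fields(cfg0)
  expect_equal(f0$illum_field, matrix(255, 64, 64))

  cfg1 <- synth_config(seed = 5, eps_range = c(1, 1), height = 64, width = 64)
  f1 <- make_degradation_fields(cfg1)
  expect_equal(f1$eps_field, matrix(1, 64, 64))

  for (seed in 0:19) {
    cfg <- synth_config(seed = seed, severity = "severe",
                        height = 80, width = 100)
    f <- make_degradation_fields(cfg)
    expect_gte(min(f$eps_field), cfg$eps_range[1])
    expect_lte(max(f$eps_field), cfg$eps_range[2])
    expect_gt(min(f$illum_field), 0)
    expect_lte(max(f$illum_field), 255)
  }
})

test_that("forward degradation follows the scattering mixture exactly", {
  cfg <- synth_config(seed = 1, noise_sigma = 0, height = 32, width = 32)
  clean <- matrix(40, 32, 32)
  eps <- matrix(0.5, 32, 32)
  illum <- matrix(200, 32, 32)
  expect_equal(apply_degradation(clean, eps, illum, cfg),
               matrix(120, 32, 32))

  # eps == 1 and no noise reproduce the clean image
  p <- generate_vein_pattern(cfg)
  expect_equal(apply_degradation(p$clean, matrix(1, 32, 32),
                                 matrix(180, 32, 32), cfg), p$clean)

  # pixelwise model residual bounded by rounding when noiseless
  f <- make_degradation_fields(cfg)
  deg <- apply_degradation(p$clean, f$eps_field, f$illum_field, cfg)
  model <- p$clean * f$eps_field + f$illum_field * (1 - f$eps_field)
  expect_lte(max(abs(deg - pmin(pmax(model, 0), 255))), 0.5)

  expect_error(apply_degradation(p$clean, matrix(1, 2, 2), illum, cfg),
               "dimensions")
})

test_that("degradation shrinks vein/background contrast whenever eps < 1", {
  for (sev in c("mild", "moderate", "severe")) {
    s <- synth_sample(synth_config(seed = 11, severity = sev,
                                   height = 96, width = 128))
    gap_clean <- mean(s$clean[!s$vein_mask]) - mean(s$clean[s$vein_mask])
    gap_deg <- mean(s$degraded[!s$vein_mask]) - mean(s$degraded[s$vein_mask])
    expect_lt(gap_deg, gap_clean)
  }
})

test_that("the severe preset lands in the heavily-degraded regime", {
  # mean vein/background gap under severe degradation stays below the
  # 50-gray-level mark that characterizes severely scattered vein images
  gaps <- sapply(0:9, function(seed) {
    s <- synth_sample(synth_config(seed = seed, severity = "severe"))
    mean(s$degraded[!s$vein_mask]) - mean(s$degraded[s$vein_mask])
  })
  expect_lt(mean(gaps), 50)
})

test_that("dataset generation writes deterministic paired files and a manifest", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- synth_config(seed = 42, height = 48, width = 64)
  samples <- generate_dataset(cfg, n = 3, dir = dir1)
  expect_length(samples, 3)
  expect_setequal(list.files(dir1),
                  c(paste0("clean_", sprintf("%04d", 0:2), ".png"),
                    paste0("degraded_", sprintf("%04d", 0:2), ".png"),
                    paste0("mask_", sprintf("%04d", 0:2), ".png"),
                    "manifest.tsv"))
  man <- read.delim(file.path(dir1, "manifest.tsv"))
  expect_equal(man$seed, 42:44)

  generate_dataset(cfg, n = 3, dir = dir2)
  for (f in list.files(dir1)) {
    expect_identical(readBin(file.path(dir1, f), "raw", 1e6),
                     readBin(file.path(dir2, f), "raw", 1e6),
                     label = f)
  }

  # files roundtrip to the in-memory sample
  back <- read_gray_image(file.path(dir1, "degraded_0001.png"))
  expect_equal(back, samples[[2]]$degraded)
})
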