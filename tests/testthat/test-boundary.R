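test_that("scale space of a monotone spectrum has no interior minima at any scale", {
  set.seed(21)
  mag <- cumsum(abs(rnorm(64)))
  ss <- gaussian_scale_space(mag)
  expect_true(all(lengths(ss$minima_by_scale) == 0))
  expect_equal(nrow(ss$tracks), 0)
})

test_that("two spectral bumps leave one persistent minima track between them", {
  mag <- exp(-((1:128) - 20)^2 / 50) + exp(-((1:128) - 80)^2 / 50)
  ss <- gaussian_scale_space(mag)
  thr <- otsu_threshold(ss$tracks$persistence)
  keep <- ss$tracks[ss$tracks$persistence > thr, ]
  between <- keep$index[keep$index > 20 & keep$index < 80]
  expect_length(between, 1)
  # brute-force scan: the raw between-bump minimum
  oracle <- which.min(mag[21:79]) + 20
  expect_lt(abs(between - oracle), 3)
})

test_that("the number of minima never increases with the scale parameter", {
  set.seed(22)
  for (r in 1:6) {
    mag <- abs(rnorm(128)) + 3 * exp(-((1:128) - sample(30:90, 1))^2 / 50)
    counts <- lengths(gaussian_scale_space(mag)$minima_by_scale)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("Otsu threshold maximises between-class variance over the length histogram", {
  thr <- otsu_threshold(c(1, 1, 1, 10, 10, 10))
  expect_gt(thr, 1)
  expect_lt(thr, 10)
  # exhaustive oracle: the returned threshold attains the maximal
  # between-class variance over a fine candidate grid
  bcv <- function(x, t) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(lo) || !length(hi)) return(-Inf)
    length(lo) / length(x) * length(hi) / length(x) * (mean(lo) - mean(hi))^2
  }
  for (lengths in list(c(1, 1, 1, 10, 10, 10), c(2, 9), c(1, 2, 3, 20, 22, 25, 3))) {
    thr <- otsu_threshold(lengths)
    grid <- seq(min(lengths), max(lengths), length.out = 400)
    expect_gte(bcv(lengths, thr) + 1e-12, max(vapply(grid, function(t) bcv(lengths, t), numeric(1))))
  }
  expect_equal(otsu_threshold(c(4, 4, 4)), 3.5)  # degenerate single class
  expect_fbewt_error(otsu_threshold(numeric(0)), "fbewt_invalid_argument")
})

test_that("boundaries land in the spectral gaps of a four-band signal", {
  set.seed(23)
  # four narrowband groups with gaps centred near 0.25, 0.5 and 0.75 pi
  # (FB bins 32 / 64 / 96 for S = 128)
  x <- tone_epoch(c(4, 10, 24, 40, 56), amps = rep(1, 5), noise_sd = 0.05)
  b <- detect_boundaries(fbse_transform(x, 128), 4)
  expect_length(b$omegas, 3)
  expect_equal(b$n_modes, 4)
  gaps <- pi * c(32, 64, 96) / 128
  for (j in 1:3) {
    expect_lt(abs(b$omegas[j] - gaps[j]), 0.05 * pi)
  }
  # deterministic for a fixed input
  b2 <- detect_boundaries(fbse_transform(x, 128), 4)
  expect_identical(b$indices, b2$indices)
})

test_that("a two-bump spectrum with two modes requested yields the between-bump minimum", {
  mag <- exp(-((1:128) - 30)^2 / 60) + exp(-((1:128) - 90)^2 / 60)
  b <- detect_boundaries(mag, 2)
  expect_length(b$indices, 1)
  oracle <- which.min(mag[31:89]) + 30
  expect_lt(abs(b$indices - oracle), 4)
})

test_that("missing persistent minima are supplemented by equal-width splitting", {
  # strictly decreasing spectrum: no interior minima at any scale
  mag <- exp(-(1:128) / 20)
  b <- detect_boundaries(mag, 4)
  expect_length(b$indices, 3)
  expect_equal(b$indices, c(32, 64, 96))
  expect_true(all(b$omegas > 0 & b$omegas < pi))
})

test_that("boundary detection validates its inputs", {
  expect_fbewt_error(detect_boundaries(abs(rnorm(32)), 1), "fbewt_invalid_argument")
  expect_fbewt_error(detect_boundaries(abs(rnorm(6)), 4), "fbewt_invalid_input")
  expect_fbewt_error(gaussian_scale_space(1:2), "fbewt_invalid_argument")
  expect_fbewt_error(gaussian_scale_space(abs(rnorm(32)), W = 8), "fbewt_invalid_argument")
  expect_fbewt_error(gaussian_scale_space(abs(rnorm(32)), eps_max = 0), "fbewt_invalid_argument")
})
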