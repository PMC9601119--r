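test_that("the Meyer auxiliary polynomial satisfies its boundary and symmetry identities", {
  expect_equal(meyer_auxiliary(0.5), 0.5)
  expect_equal(meyer_auxiliary(-1), 0)
  expect_equal(meyer_auxiliary(2), 1)
  x <- seq(0, 1, by = 0.05)
  expect_equal(meyer_auxiliary(x) + meyer_auxiliary(1 - x), rep(1, length(x)))
  expect_true(all(diff(meyer_auxiliary(x)) >= 0))
})

test_that("a single-boundary bank has the printed plateaus and rolls off through the transition", {
  bank <- build_filter_bank(pi / 2, tau = 0.1)
  grid <- bank$grid
  expect_equal(bank$phi[grid <= 0.45 * pi], rep(1, sum(grid <= 0.45 * pi)))
  expect_lt(max(abs(bank$phi[grid >= 0.55 * pi])), 1e-12)
  expect_lt(max(abs(bank$nus[grid <= 0.45 * pi, 1])), 1e-12)
  # last wavelet is high-pass: plateau from the end of the transition to pi
  expect_equal(bank$nus[grid >= 0.55 * pi, 1], rep(1, sum(grid >= 0.55 * pi)),
               tolerance = 1e-12)
  expect_true(all(bank$phi >= 0 & bank$phi <= 1))
})

test_that("squared responses form a partition of unity for banks on detected boundaries", {
  # fixed banks
  for (om in list(pi / 2, c(0.2, 0.5, 0.8) * pi, c(0.1, 0.35, 0.6, 0.9) * pi)) {
    bank <- build_filter_bank(om)
    total <- bank$phi^2 + rowSums(bank$nus^2)
    expect_lt(max(abs(total - 1)), 1e-6)
  }
  # banks built from detect_boundaries output of random epochs
  set.seed(31)
  for (r in 1:50) {
    x <- tone_epoch(sort(runif(4, 3, 58)), noise_sd = 0.2)
    bank <- build_filter_bank(detect_boundaries(fbse_transform(x, 128), 4))
    total <- bank$phi^2 + rowSums(bank$nus^2)
    expect_lt(max(abs(total - 1)), 1e-6)
  }
})

test_that("the transition width respects the frame condition", {
  expect_fbewt_error(build_filter_bank(c(0.4, 0.5) * pi, tau = 0.5),
                     "fbewt_invalid_argument")
  # default tau is 0.9 of the bound over consecutive pairs including pi
  om <- c(0.3, 0.6) * pi
  bound <- min((0.6 - 0.3) / (0.6 + 0.3), (1 - 0.6) / (1 + 0.6))
  expect_equal(build_filter_bank(om)$tau, 0.9 * bound)
  expect_fbewt_error(build_filter_bank(c(0.5, 0.2) * pi), "fbewt_invalid_argument")
  expect_fbewt_error(build_filter_bank(c(0.2, 1.2) * pi), "fbewt_invalid_argument")
})

test_that("decomposition reconstructs the epoch and separates bands", {
  set.seed(32)
  bank <- build_filter_bank(c(0.25, 0.5, 0.75) * pi, tau = 0.1)
  # zero epoch -> all-zero components
  z <- ewt_decompose(numeric(128), bank)
  expect_equal(mode_matrix(z), matrix(0, 128, 4, dimnames = list(NULL, paste0("mode", 1:4))),
               ignore_attr = TRUE)
  # r0 + sum of modes recovers random epochs
  for (S in c(64, 128, 256)) {
    for (r in 1:5) {
      x <- rnorm(S)
      md <- ewt_decompose(x, bank)
      rec <- md$r0 + rowSums(md$modes)
      expect_lt(sqrt(sum((rec - x)^2) / sum(x^2)), 1e-6)
      expect_equal(ncol(mode_matrix(md)), 4)
    }
  }
  # a 0.8*pi sinusoid with one boundary at 0.5*pi lands in the wavelet mode
  b1 <- build_filter_bank(pi / 2, tau = 0.1)
  x <- sin(2 * pi * 51.2 * (0:127) / 128)   # normalised frequency 0.8*pi
  md <- ewt_decompose(x, b1)
  expect_gt(sum(md$modes[, 1]^2) / sum(x^2), 0.99)
  expect_lt(sum(md$r0^2) / sum(x^2), 0.01)
})

test_that("decomposition is linear and nearly leakage-free for well-separated tones", {
  set.seed(33)
  bank <- build_filter_bank(c(0.4, 0.7) * pi)
  a <- rnorm(128)
  b <- rnorm(128)
  ma <- mode_matrix(ewt_decompose(a, bank))
  mb <- mode_matrix(ewt_decompose(b, bank))
  mab <- mode_matrix(ewt_decompose(a + b, bank))
  expect_lt(max(abs(mab - (ma + mb))), 1e-9)
  # two tones in different bands: cross-band leakage < 1% of total energy
  x1 <- sin(2 * pi * 12.8 * (0:127) / 128)   # 0.2*pi, below first boundary
  x2 <- sin(2 * pi * 57.6 * (0:127) / 128)   # 0.9*pi, above second boundary
  md <- ewt_decompose(x1 + x2, bank)
  tot <- sum((x1 + x2)^2)
  leak <- sum(md$modes[, 1]^2)               # middle band holds neither tone
  expect_lt(leak / tot, 0.01)
})

test_that("decompose validates its inputs", {
  bank <- build_filter_bank(pi / 2)
  expect_fbewt_error(ewt_decompose(rnorm(4), bank), "fbewt_invalid_input")
  expect_error(ewt_decompose(rnorm(32), list()), "fbewt_bank")
})
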