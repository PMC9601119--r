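test_that("zero-order Bessel roots match a bisection oracle and the asymptotic spacing", {
  roots <- bessel_j0_roots(100)
  expect_equal(roots[1], 2.4048255577, tolerance = 1e-9)
  expect_true(all(diff(roots) > 0))
  # spacing approaches pi
  expect_lt(abs((roots[50] - roots[49]) - pi), 0.01)
  # bisection oracle on [i*pi - pi/2, i*pi + pi/2]
  bisect_root <- function(i) {
    lo <- i * pi - pi / 2
    hi <- i * pi + pi / 2
    for (iter in 1:80) {
      mid <- (lo + hi) / 2
      if (besselJ(lo, 0) * besselJ(mid, 0) <= 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  oracle <- vapply(1:100, bisect_root, numeric(1))
  expect_equal(roots, oracle, tolerance = 1e-9)
  expect_fbewt_error(bessel_j0_roots(0), "fbewt_invalid_argument")
  expect_fbewt_error(bessel_j0_roots(-3), "fbewt_invalid_argument")
})

test_that("quadrature transform reproduces the explicit double-loop coefficient formula", {
  set.seed(101)
  S <- 32
  s <- rnorm(S)
  sp <- fbse_transform(s, fs = 128, method = "quadrature")
  roots <- bessel_j0_roots(S)
  oracle <- vapply(seq_len(S), function(i) {
    acc <- 0
    for (n in 0:(S - 1)) {
      acc <- acc + n * s[n + 1] * besselJ(roots[i] * n / S, 0)
    }
    2 / (S^2 * besselJ(roots[i], 1)^2) * acc
  }, numeric(1))
  expect_equal(sp$coefficients, oracle, tolerance = 1e-12)
})

test_that("the FBSE spectrum localises basis-aligned content and spans [0, fs/2] with S points", {
  S <- 64
  roots <- bessel_j0_roots(S)
  s <- besselJ(roots[3] * (0:(S - 1)) / S, 0)
  for (m in c("collocation", "quadrature")) {
    sp <- fbse_transform(s, fs = 128, method = m)
    expect_equal(which.max(abs(sp$coefficients)), 3)
  }
  sp <- fbse_transform(s, fs = 128)
  expect_length(sp$freq_grid, S)              # twice the DFT half-spectrum density
  expect_true(all(diff(sp$freq_grid) > 0))
  expect_equal(sp$freq_grid[S], 64)
  # all-zero signal has an identically zero spectrum
  z <- fbse_transform(numeric(64), fs = 128)
  expect_equal(z$coefficients, numeric(64))
})

test_that("analysis followed by the synthesis sum reconstructs signals to near machine precision", {
  set.seed(7)
  for (S in c(32, 64, 128, 256, 512)) {
    s <- rnorm(S)
    sp <- fbse_transform(s, fs = S)
    rec <- fbse_synthesize(sp)
    expect_lt(max(abs(rec - s)), 1e-8)
    expect_lt(sqrt(sum((rec - s)^2) / sum(s^2)), 1e-6)
  }
})

test_that("transform validates its inputs", {
  expect_fbewt_error(fbse_transform(c(1, NA, 3), 128), "fbewt_invalid_input")
  expect_fbewt_error(fbse_transform(c(1, Inf, 3), 128), "fbewt_invalid_input")
  expect_fbewt_error(fbse_transform(1, 128), "fbewt_invalid_argument")
  expect_fbewt_error(fbse_transform(rnorm(16), -1), "fbewt_invalid_argument")
})

test_that("order-to-frequency mapping is the linear half-spectrum rule", {
  expect_equal(order_to_frequency(2, S = 128, fs = 128), 1.0)
  expect_equal(order_to_frequency(128, S = 128, fs = 128), 64)   # fs / 2
  f <- order_to_frequency(1:64, S = 64, fs = 256)
  expect_true(all(diff(f) > 0))
  expect_fbewt_error(order_to_frequency(0, 64, 128), "fbewt_invalid_argument")
  expect_fbewt_error(order_to_frequency(65, 64, 128), "fbewt_invalid_argument")
})

test_that("energy spectrum matches term-by-term evaluation and localises with the coefficients", {
  set.seed(11)
  s <- rnorm(32)
  sp <- fbse_transform(s, fs = 64)
  E <- energy_spectrum(sp)
  roots <- bessel_j0_roots(32)
  oracle <- sp$coefficients^2 * 32^2 * vapply(roots, function(b) besselJ(b, 1), numeric(1))^2 / 2
  expect_equal(E, oracle, tolerance = 1e-12)
  expect_true(all(E >= 0))
  # a single nonzero coefficient gives a single nonzero energy at the same order
  sp$coefficients <- replace(numeric(32), 17, 2.5)
  E1 <- energy_spectrum(sp)
  expect_equal(which(E1 > 0), 17)
})
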