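fs <- 256

test_that("Fourier coefficients are amplitude-calibrated on the 1 Hz grid", {
  t <- seq_len(fs) / fs
  x <- array(0, dim = c(2, 1, fs))
  x[1, 1, ] <- cos(2 * pi * 10 * t)
  e <- epochs_from_array(x, fs)
  s <- fourier_coefficients(e)
  expect_equal(Mod(s$coeffs[1, 1, 10]), 0.5, tolerance = 1e-12)
  expect_lt(max(Mod(s$coeffs[1, 1, -10])), 1e-12)
  # zero epoch -> all-zero coefficients
  expect_equal(max(Mod(s$coeffs[2, 1, ])), 0)
  expect_equal(s$freqs, 1:100)
})

test_that("coefficients satisfy Parseval for band-limited signals", {
  t <- seq_len(fs) / fs
  sig <- 1.3 * cos(2 * pi * 7 * t + 0.4) + 0.6 * sin(2 * pi * 41 * t)
  e <- epochs_from_array(array(sig, dim = c(1, 1, fs)), fs)
  s <- fourier_coefficients(e)
  expect_equal(sum(2 * Mod(s$coeffs[1, 1, ])^2), mean(sig^2),
               tolerance = 1e-10)
})

test_that("off-grid frequencies are rejected", {
  e <- epochs_from_array(array(rnorm(2 * fs), dim = c(2, 1, fs)), fs)
  expect_error(fourier_coefficients(e, freqs = c(10.5, 20)), "grid")
  s <- fourier_coefficients(e)
  expect_error(higher_order_autospectrum(s, 1, 200, 1), "grid")
})

test_that("frequency-pair enumeration follows the common-factor rule", {
  pairs <- enumerate_pairs()
  key <- function(fx, fy) which(pairs$f_x == fx & pairs$f_y == fy)
  p <- pairs[key(10, 20), ]
  expect_equal(c(p$n, p$m), c(1L, 2L))
  expect_equal(p$kind, "nonlinear")
  wide <- enumerate_pairs(c(1L, 100L), c(10L, 100L))
  p <- wide[wide$f_x == 21 & wide$f_y == 14, ]  # f_y below the EMG default
  expect_equal(c(p$n, p$m), c(3L, 2L))
  expect_length(key(7, 13), 0)           # coprime pair excluded
  p <- pairs[key(25, 25), ]
  expect_equal(c(p$n, p$m, p$kind), c("1", "1", "linear"))
  expect_length(key(1, 20), 0)           # f_x = 1 shares no factor > 1
  # linear pairs cover exactly the range intersection
  expect_equal(pairs$f_x[pairs$kind == "linear"], 20:100)
  # n:m is in lowest terms and consistent with the frequency ratio
  expect_true(all(mapply(bmconn:::gcd2, pairs$n, pairs$m) == 1L))
  expect_true(all(pairs$n * pairs$f_y == pairs$m * pairs$f_x))
  # deterministic ordering
  expect_true(!is.unsorted(pairs$f_x))
})

test_that("pair count matches a brute-force traversal oracle", {
  slow_gcd <- function(a, b) {
    g <- 1L
    for (d in seq_len(min(a, b))) if (a %% d == 0L && b %% d == 0L) g <- d
    g
  }
  count <- 0L
  for (fx in 1:100) {
    for (fy in 20:100) {
      if (fx == fy || slow_gcd(fx, fy) > 1L) count <- count + 1L
    }
  }
  expect_equal(nrow(enumerate_pairs()), count)
})

test_that("higher-order auto-spectra generalize the power spectrum", {
  e <- epochs_from_array(array(rnorm(20 * 2 * fs), dim = c(20, 2, fs)), fs)
  s <- fourier_coefficients(e)
  # p = 1 is the ordinary epoch-averaged periodogram value
  expect_equal(higher_order_autospectrum(s, 2, 15, 1),
               mean(Mod(s$coeffs[, 2, 15])^2))
  # p = 2 equals the mean squared periodogram, by brute-force recomputation
  per <- vapply(1:20, function(l) Mod(s$coeffs[l, 1, 30])^2, numeric(1))
  expect_equal(higher_order_autospectrum(s, 1, 30, 2), mean(per^2),
               tolerance = 1e-12)
  # constant modulus c across epochs gives c^(2p)
  cst <- array(complex(modulus = 2, argument = runif(12)), c(12, 1, 1))
  s2 <- structure(list(coeffs = cst, freqs = 5L, labels = "a",
                       taper = "rectangular", fs = fs, epoch_length = 1),
                  class = "bmc_spectra")
  expect_equal(higher_order_autospectrum(s2, 1, 5, 3), 2^6,
               tolerance = 1e-12)
})

test_that("phase-locked 1:2 harmonics give unit cross-spectral connectivity", {
  set.seed(42)
  h <- harmonic_epochs(runif(16, 0, 2 * pi), f = 10, ratio = 2, fs = fs)
  sx <- fourier_coefficients(h$x)
  sy <- fourier_coefficients(h$y)
  pair <- data.frame(f_x = 10L, f_y = 20L, n = 1L, m = 2L,
                     kind = "nonlinear")
  expect_equal(csc(sx, sy, pair), 1, tolerance = 1e-9)
  # the cross-spectrum phase terms align epoch by epoch
  cs <- cross_spectrum(sx, sy, pair)
  expect_equal(Mod(cs), 0.5^3, tolerance = 1e-9)  # |X|^2 |Y| = 0.125
})

test_that("self-coherence at n = m = 1 is exactly one", {
  set.seed(7)
  x <- array(rnorm(10 * fs), dim = c(10, 1, fs))
  e <- epochs_from_array(x, fs)
  s <- fourier_coefficients(e)
  pair <- data.frame(f_x = 25L, f_y = 25L, n = 1L, m = 1L, kind = "linear")
  expect_equal(csc(s, s, pair), 1, tolerance = 1e-12)
})

test_that("linear CSC equals an independent coherence oracle to 1e-12", {
  set.seed(11)
  L <- 24
  ex <- epochs_from_array(array(rnorm(L * 2 * fs), dim = c(L, 2, fs)), fs)
  ey <- epochs_from_array(array(rnorm(L * fs), dim = c(L, 1, fs)), fs)
  # inject shared content so coherence is non-trivial at 30 Hz
  t <- seq_len(fs) / fs
  for (l in seq_len(L)) {
    ph <- runif(1, 0, 2 * pi)
    ex$data[l, 1, ] <- ex$data[l, 1, ] + 3 * cos(2 * pi * 30 * t + ph)
    ey$data[l, 1, ] <- ey$data[l, 1, ] + 2 * cos(2 * pi * 30 * t + ph + 1)
  }
  sx <- fourier_coefficients(ex)
  sy <- fourier_coefficients(ey)
  for (f in c(25L, 30L)) {
    pair <- data.frame(f_x = f, f_y = f, n = 1L, m = 1L, kind = "linear")
    expect_equal(csc(sx, sy, pair, channel_x = 1L),
                 coherence_oracle(ex, ey, f), tolerance = 1e-12)
  }
  # the map agrees with per-pair evaluation across channels and kinds
  pairs <- enumerate_pairs(c(20L, 40L), c(20L, 40L))
  cm <- csc_map(sx, sy, pairs)
  for (j in c(1L, 5L, nrow(pairs))) {
    for (ch in 1:2) {
      expect_equal(cm$values[ch, j],
                   csc(sx, sy, pairs[j, ], channel_x = ch),
                   tolerance = 1e-12)
    }
  }
})

test_that("CSC stays within [0, 1] across random inputs and orders", {
  set.seed(3)
  L <- 12
  ex <- epochs_from_array(array(rnorm(L * 3 * fs), dim = c(L, 3, fs)), fs)
  ey <- epochs_from_array(array(rnorm(L * fs), dim = c(L, 1, fs)), fs)
  cm <- csc_map(fourier_coefficients(ex), fourier_coefficients(ey),
                enumerate_pairs())
  expect_true(all(cm$values >= 0 & cm$values <= 1))
})

test_that("an all-zero EMG yields missing connectivity, not spurious values", {
  L <- 6
  ex <- epochs_from_array(array(rnorm(L * fs), dim = c(L, 1, fs)), fs)
  ey <- epochs_from_array(array(0, dim = c(L, 1, fs)), fs)
  suppressMessages({
    cm <- csc_map(fourier_coefficients(ex), fourier_coefficients(ey),
                  enumerate_pairs(c(20L, 25L), c(20L, 25L)))
  })
  expect_true(all(is.na(cm$values)))
})

test_that("under independence, mean CSC shrinks as epochs accumulate", {
  set.seed(19)
  pairs <- enumerate_pairs(c(20L, 30L), c(20L, 30L))
  means <- vapply(c(8L, 64L, 512L), function(L) {
    ex <- epochs_from_array(array(rnorm(L * 64), dim = c(L, 1, 64)), 64)
    ey <- epochs_from_array(array(rnorm(L * 64), dim = c(L, 1, 64)), 64)
    cm <- csc_map(fourier_coefficients(ex), fourier_coefficients(ey), pairs)
    mean(cm$values)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("the permutation null is deterministic and brackets independence", {
  set.seed(23)
  L <- 40
  ex <- epochs_from_array(array(rnorm(L * fs), dim = c(L, 1, fs)), fs)
  ey <- epochs_from_array(array(rnorm(L * fs), dim = c(L, 1, fs)), fs)
  sx <- fourier_coefficients(ex)
  sy <- fourier_coefficients(ey)
  pair <- data.frame(f_x = 12L, f_y = 24L, n = 1L, m = 2L,
                     kind = "nonlinear")
  n1 <- permutation_null(sx, sy, pair, n_perm = 150, seed = 5L)
  n2 <- permutation_null(sx, sy, pair, n_perm = 150, seed = 5L)
  expect_identical(n1$percentiles, n2$percentiles)
  expect_false(identical(
    n1$values, permutation_null(sx, sy, pair, n_perm = 150, seed = 6L)$values
  ))
  # phase-locked data exceed the 99th null percentile
  h <- harmonic_epochs(runif(30, 0, 2 * pi), f = 12, ratio = 2, fs = fs)
  shx <- fourier_coefficients(h$x)
  shy <- fourier_coefficients(h$y)
  nl <- permutation_null(shx, shy, pair, n_perm = 150, seed = 9L)
  expect_gt(nl$observed, unname(nl$percentiles["99%"]))
  # contract errors
  tiny <- epochs_from_array(array(rnorm(2 * fs), dim = c(2, 1, fs)), fs)
  st <- fourier_coefficients(tiny)
  expect_error(permutation_null(st, st, pair, n_perm = 150), "3 epochs")
  expect_error(permutation_null(sx, sy, pair, n_perm = 50), "100")
})
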