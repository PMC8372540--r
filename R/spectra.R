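#' Per-epoch Fourier coefficients on the integer frequency grid
#'
#' Computes, for every epoch and channel, the (tapered) discrete Fourier
#' transform evaluated at an integer grid of frequencies. Coefficients are
#' scaled so that a unit-amplitude sinusoid at a grid frequency with the
#' rectangular taper yields |coefficient| = 0.5 (i.e. FFT divided by the
#' taper sum). With 1 s epochs the grid resolution is exactly 1 Hz.
#'
#' @param e a `bmc_epochs` object
#' @param taper "rectangular" or "hann"
#' @param freqs integer grid in Hz; defaults to 1 Hz steps up to 100 Hz
#'   (clipped below the Nyquist frequency)
#' @return object of class `bmc_spectra`: complex `coeffs`
#'   [n_epochs x n_channels x n_freqs], `freqs`, `labels`, `taper`, `fs`,
#'   `epoch_length`
#' @export
fourier_coefficients <- function(e, taper = c("rectangular", "hann"),
                                 freqs = NULL) {
  stopifnot(inherits(e, "bmc_epochs"))
  taper <- match.arg(taper)
  len <- dim(e$data)[3]
  if (is.null(freqs)) {
    freqs <- seq_len(min(100, floor((e$fs / 2 - 1))))
  }
  bins <- freqs * e$epoch_length
  if (any(abs(bins - round(bins)) > 1e-9)) {
    stop("frequencies must be multiples of the 1/epoch_length grid (",
         signif(1 / e$epoch_length, 3), " Hz)")
  }
  bins <- as.integer(round(bins))
  if (any(bins < 1L) || any(bins > floor(len / 2))) {
    stop("requested frequencies fall outside the resolvable grid")
  }
  w <- switch(taper,
              rectangular = rep(1, len),
              hann = 0.5 - 0.5 * cos(2 * pi * seq_len(len) / (len + 1)))
  scale <- sum(w)
  n_ep <- dim(e$data)[1]
  n_ch <- dim(e$data)[2]
  coeffs <- array(complex(real = 0), dim = c(n_ep, n_ch, length(freqs)))
  for (ch in seq_len(n_ch)) {
    seg <- e$data[, ch, , drop = FALSE]
    dim(seg) <- c(n_ep, len)
    seg <- sweep(seg, 2L, w, `*`)
    # mvfft works column-wise: transpose so each epoch is one column
    ft <- stats::mvfft(t(seg)) / scale
    coeffs[, ch, ] <- t(ft[bins + 1L, , drop = FALSE])
  }
  structure(
    list(coeffs = coeffs, freqs = freqs, labels = e$labels, taper = taper,
         fs = e$fs, epoch_length = e$epoch_length),
    class = "bmc_spectra"
  )
}

#' @export
print.bmc_spectra <- function(x, ...) {
  d <- dim(x$coeffs)
  cat("<bmc_spectra> ", d[1], " epochs x ", d[2], " channels x ", d[3],
      " frequencies (", min(x$freqs), "-", max(x$freqs), " Hz, ",
      x$taper, " taper)\n", sep = "")
  invisible(x)
}

#' Enumerate linear and nonlinear frequency pairs
#'
#' Traverses all integer frequencies f_x in the EEG range and f_y in the
#' EMG range. Linear (iso-frequency) pairs are all f_x = f_y in the range
#' intersection. Nonlinear (cross-frequency) pairs are all f_x != f_y whose
#' greatest common divisor g exceeds 1; the coupling order is n = f_x / g,
#' m = f_y / g, coprime with n : m = f_x : f_y. The list is deterministic,
#' sorted by (f_x, f_y).
#'
#' @param eeg_range integer bounds for f_x, Hz
#' @param emg_range integer bounds for f_y, Hz
#' @return data.frame with columns f_x, f_y, n, m, kind
#' @export
enumerate_pairs <- function(eeg_range = c(1L, 100L),
                            emg_range = c(20L, 100L)) {
  stopifnot(length(eeg_range) == 2L, length(emg_range) == 2L)
  fx <- seq.int(eeg_range[1], eeg_range[2])
  fy <- seq.int(emg_range[1], emg_range[2])
  grid <- expand.grid(f_x = fx, f_y = fy, KEEP.OUT.ATTRS = FALSE)
  g <- mapply(gcd2, grid$f_x, grid$f_y)
  linear <- grid$f_x == grid$f_y
  keep <- linear | g > 1L
  grid <- grid[keep, , drop = FALSE]
  g <- g[keep]
  out <- data.frame(
    f_x = as.integer(grid$f_x),
    f_y = as.integer(grid$f_y),
    n = as.integer(grid$f_x / g),
    m = as.integer(grid$f_y / g),
    kind = ifelse(grid$f_x == grid$f_y, "linear", "nonlinear")
  )
  out <- out[order(out$f_x, out$f_y), , drop = FALSE]
  rownames(out) <- NULL
  out
}

gcd2 <- function(a, b) {
  while (b != 0L) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

freq_index <- function(s, f) {
  i <- match(f, s$freqs)
  if (is.na(i)) stop("frequency ", f, " Hz is not on the spectral grid")
  i
}

#' Higher-order auto-spectrum
#'
#' Epoch-averaged 2p-th absolute power of a channel's Fourier coefficient:
#' (1/L) * sum_l |X_l(f)|^(2p). Order p = 1 is the ordinary power spectral
#' estimate; higher orders normalize the n:m cross-spectrum.
#'
#' @param s a `bmc_spectra`
#' @param channel channel index or label
#' @param f frequency on the grid, Hz
#' @param p order (integer >= 1)
#' @return non-negative scalar
#' @export
higher_order_autospectrum <- function(s, channel, f, p) {
  stopifnot(inherits(s, "bmc_spectra"), p >= 1)
  if (is.character(channel)) channel <- match(channel, s$labels)
  i <- freq_index(s, f)
  mean(Mod(s$coeffs[, channel, i])^(2 * p))
}

#' Phase-matched n:m cross-spectrum
#'
#' For a frequency pair (f_x, f_y) with coprime order n : m = f_x : f_y,
#' averages over epochs the product X_l(f_x)^m * conj(Y_l(f_y))^n. Raising
#' X to m and Y to n makes both factors rotate at the common frequency
#' m * f_x = n * f_y, so a consistent n:m phase relation accumulates
#' coherently across epochs. At n = m = 1 this is the ordinary
#' cross-spectral estimate.
#'
#' @param sx,sy `bmc_spectra` with identical epoch counts and alignment
#' @param pair one row of [enumerate_pairs()] (or a list with f_x, f_y,
#'   n, m)
#' @param channel_x,channel_y channel index or label in `sx` / `sy`
#' @return complex scalar
#' @export
cross_spectrum <- function(sx, sy, pair, channel_x = 1L, channel_y = 1L) {
  L <- dim(sx$coeffs)[1]
  if (dim(sy$coeffs)[1] != L) {
    stop("sx and sy must have the same epoch count (", L, " vs ",
         dim(sy$coeffs)[1], ")")
  }
  if (is.character(channel_x)) channel_x <- match(channel_x, sx$labels)
  if (is.character(channel_y)) channel_y <- match(channel_y, sy$labels)
  x <- sx$coeffs[, channel_x, freq_index(sx, pair$f_x)]
  y <- sy$coeffs[, channel_y, freq_index(sy, pair$f_y)]
  mean(x^pair$m * Conj(y^pair$n))
}

#' Cross-spectral connectivity (CSC) at one frequency pair
#'
#' The magnitude of the phase-matched n:m cross-spectrum normalized by the
#' square-rooted product of the matching higher-order auto-spectra:
#'
#' CSC = |(1/L) sum X^m conj(Y)^n| /
#'       sqrt( (1/L) sum |X|^(2m) * (1/L) sum |Y|^(2n) )
#'
#' which lies in [0, 1] by the Cauchy-Schwarz inequality and reduces to the
#' classical magnitude coherence (corticomuscular coherence) at n = m = 1.
#' A silent channel (zero denominator) yields NA.
#'
#' @inheritParams cross_spectrum
#' @return scalar in [0, 1], or NA when undefined
#' @export
csc <- function(sx, sy, pair, channel_x = 1L, channel_y = 1L) {
  L <- dim(sx$coeffs)[1]
  if (L < 2L) stop("CSC requires at least 2 epochs")
  if (is.character(channel_x)) channel_x <- match(channel_x, sx$labels)
  if (is.character(channel_y)) channel_y <- match(channel_y, sy$labels)
  x <- sx$coeffs[, channel_x, freq_index(sx, pair$f_x)]
  y <- sy$coeffs[, channel_y, freq_index(sy, pair$f_y)]
  csc_kernel(x, y, pair$n, pair$m)
}

# numerically stabilized CSC: the statistic is invariant to per-channel
# rescaling of X and Y, so both are normalized to unit RMS before raising
# to the coupling orders, preventing under/overflow at high n or m
csc_kernel <- function(x, y, n, m) {
  rx <- sqrt(mean(Mod(x)^2))
  ry <- sqrt(mean(Mod(y)^2))
  if (rx == 0 || ry == 0) return(NA_real_)
  xm <- (x / rx)^m
  yn <- (y / ry)^n
  den <- sqrt(mean(Mod(xm)^2) * mean(Mod(yn)^2))
  if (!is.finite(den) || den == 0) return(NA_real_)
  Mod(mean(xm * Conj(yn))) / den
}

#' CSC over all EEG channels and frequency pairs
#'
#' Vectorized evaluation of [csc()] over a channel set and a pair list,
#' producing the connectivity map the N-L index is built from.
#'
#' @param sx `bmc_spectra` for the EEG channels
#' @param sy `bmc_spectra` for the (single-channel) EMG
#' @param pairs data.frame from [enumerate_pairs()]
#' @param channel_y EMG channel index in `sy`
#' @return object of class `bmc_cmap`: `values`
#'   [n_eeg_channels x n_pairs] in [0, 1] (NA where undefined), `pairs`,
#'   `labels`, epoch count `L`
#' @export
csc_map <- function(sx, sy, pairs, channel_y = 1L) {
  L <- dim(sx$coeffs)[1]
  if (L < 2L) stop("CSC requires at least 2 epochs")
  if (dim(sy$coeffs)[1] != L) stop("epoch counts differ between sx and sy")
  n_ch <- dim(sx$coeffs)[2]
  vals <- matrix(NA_real_, n_ch, nrow(pairs))
  y_all <- sy$coeffs[, channel_y, , drop = FALSE]
  dim(y_all) <- c(L, dim(sy$coeffs)[3])
  for (j in seq_len(nrow(pairs))) {
    fxi <- freq_index(sx, pairs$f_x[j])
    fyi <- freq_index(sy, pairs$f_y[j])
    m <- pairs$m[j]
    n <- pairs$n[j]
    xm <- sx$coeffs[, , fxi, drop = FALSE]
    dim(xm) <- c(L, n_ch)
    rx <- sqrt(colMeans(Mod(xm)^2))
    rx[rx == 0] <- NA_real_
    xm <- sweep(xm, 2L, rx, `/`)^m
    y <- y_all[, fyi]
    ry <- sqrt(mean(Mod(y)^2))
    if (ry == 0) next
    yn <- (y / ry)^n
    num <- Mod(colMeans(xm * Conj(yn)))
    sxx <- colMeans(Mod(xm)^2)
    syy <- mean(Mod(yn)^2)
    den <- sqrt(sxx * syy)
    vals[, j] <- ifelse(is.finite(den) & den > 0, num / den, NA_real_)
  }
  n_missing <- sum(is.na(vals))
  if (n_missing > 0L) {
    message(n_missing, " connectivity values undefined (silent channel)")
  }
  structure(
    list(values = vals, pairs = pairs, labels = sx$labels, L = L),
    class = "bmc_cmap"
  )
}

#' @export
print.bmc_cmap <- function(x, ...) {
  cat("<bmc_cmap> ", nrow(x$values), " channels x ", nrow(x$pairs),
      " frequency pairs (", sum(x$pairs$kind == "linear"), " linear, ",
      sum(x$pairs$kind == "nonlinear"), " nonlinear), L = ", x$L,
      " epochs\n", sep = "")
  invisible(x)
}

#' Permutation null distribution for CSC
#'
#' Destroys the epoch pairing between X and Y by randomly permuting the
#' epochs of Y and recomputing the CSC, `n_perm` times. The resulting
#' distribution is the independence reference against which an observed
#' CSC can be judged. Deterministic given `seed`.
#'
#' @inheritParams cross_spectrum
#' @param n_perm number of permutations (>= 100)
#' @param seed integer seed
#' @param probs percentiles to report
#' @return list with `values` (n_perm null CSCs), `percentiles`, `observed`
#' @export
permutation_null <- function(sx, sy, pair, channel_x = 1L, channel_y = 1L,
                             n_perm = 200L, seed = 1L,
                             probs = c(0.5, 0.9, 0.95, 0.99)) {
  L <- dim(sx$coeffs)[1]
  if (L < 3L) stop("permutation null requires at least 3 epochs")
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (is.character(channel_x)) channel_x <- match(channel_x, sx$labels)
  if (is.character(channel_y)) channel_y <- match(channel_y, sy$labels)
  x <- sx$coeffs[, channel_x, freq_index(sx, pair$f_x)]
  y <- sy$coeffs[, channel_y, freq_index(sy, pair$f_y)]
  rx <- sqrt(mean(Mod(x)^2))
  ry <- sqrt(mean(Mod(y)^2))
  if (rx == 0 || ry == 0) stop("silent channel: null distribution undefined")
  x <- (x / rx)^pair$m
  y <- (y / ry)^pair$n
  den <- sqrt(mean(Mod(x)^2) * mean(Mod(y)^2))
  observed <- Mod(mean(x * Conj(y))) / den
  vals <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      Mod(mean(x * Conj(y[sample.int(L)]))) / den
    }, numeric(1))
  })
  list(values = vals,
       percentiles = stats::quantile(vals, probs, names = TRUE),
       observed = observed)
}
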