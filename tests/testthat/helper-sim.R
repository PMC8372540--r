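# small-scale simulation settings shared across tests: short recordings at
# a reduced sampling rate keep the suite fast while preserving the 1 Hz
# spectral grid and the 20-100 Hz EMG band below Nyquist
quick_cfg <- function(..., n_trials = 3L, fs = 256, gap_duration = 0.5,
                      seed = 1L) {
  simulation_config(n_trials = n_trials, fs = fs,
                    gap_duration = gap_duration, seed = seed, ...)
}

# epoch container built directly from an array, for estimator tests that
# need exact analytic signals rather than simulated recordings
epochs_from_array <- function(data, fs, epoch_length = 1, overlap = 0.25,
                              labels = NULL) {
  if (is.null(labels)) labels <- paste0("ch", seq_len(dim(data)[2]))
  structure(
    list(data = data, fs = fs, epoch_length = epoch_length,
         overlap = overlap, labels = labels,
         origin = data.frame(trial = 1L, start = seq_len(dim(data)[1]))),
    class = "bmc_epochs"
  )
}

# analytic phase-locked harmonic pair: X holds cos(2 pi f t + phi_l), Y
# holds cos(2 pi (m/n) f t + (m/n) phi_l * n ... ) — i.e. a perfect n:m
# phase relation across epochs
harmonic_epochs <- function(phis, f, ratio, fs, len = fs) {
  t <- seq_len(len) / fs
  x <- t(vapply(phis, function(p) cos(2 * pi * f * t + p), numeric(len)))
  y <- t(vapply(phis, function(p) cos(2 * pi * ratio * f * t + ratio * p),
                numeric(len)))
  list(
    x = epochs_from_array(array(x, dim = c(length(phis), 1L, len)), fs),
    y = epochs_from_array(array(y, dim = c(length(phis), 1L, len)), fs)
  )
}

# independent classical magnitude-coherence oracle, computed straight from
# per-epoch FFTs of the raw epoch arrays (no shared code with the package)
coherence_oracle <- function(ex, ey, f, chx = 1L, chy = 1L) {
  L <- dim(ex$data)[1]
  len <- dim(ex$data)[3]
  bin <- f * ex$epoch_length + 1L
  sxy <- 0 + 0i
  sxx <- 0
  syy <- 0
  for (l in seq_len(L)) {
    X <- stats::fft(ex$data[l, chx, ])[bin]
    Y <- stats::fft(ey$data[l, chy, ])[bin]
    sxy <- sxy + X * Conj(Y)
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
  }
  Mod(sxy) / sqrt(sxx * syy)
}
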