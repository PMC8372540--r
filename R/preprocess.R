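#' @importFrom signal butter filtfilt filter
NULL

# forward-backward IIR filtering with odd reflection padding at both ends
# to suppress start-up transients; pad length scales with the slowest band
# edge so the reflected segment covers the filter's settling time.
zero_phase <- function(b, a, x, pad) {
  n <- length(x)
  p <- min(n - 1L, as.integer(pad))
  if (p > 0L) {
    head_pad <- 2 * x[1] - x[(p + 1L):2L]
    tail_pad <- 2 * x[n] - x[(n - 1L):(n - p)]
    xp <- c(head_pad, x, tail_pad)
  } else {
    xp <- x
  }
  y <- signal::filtfilt(signal::Arma(b = b, a = a), xp)
  y[(p + 1L):(p + n)]
}

butter_coefs <- function(order, w, type) {
  flt <- signal::butter(order, w, type = type)
  list(b = flt$b, a = flt$a)
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth high-pass and low-pass stages applied in cascade,
#' each forward and backward, so the net phase response is zero and the
#' effective attenuation slope is doubled. The cascade (rather than a single
#' band-pass prototype) keeps the recursion numerically stable when the low
#' edge is a tiny fraction of the Nyquist frequency, as with a 1 Hz edge at
#' 2048 Hz sampling.
#'
#' @param x numeric signal vector
#' @param band c(low, high) edges in Hz, 0 < low < high < fs/2
#' @param fs sampling rate in Hz
#' @param order per-stage Butterworth order
#' @return filtered signal, same length as `x`
#' @export
filter_band <- function(x, band, fs, order = 4L) {
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2] ||
      band[2] >= fs / 2) {
    stop("band must satisfy 0 < low < high < fs/2 (fs = ", fs, " Hz)")
  }
  hp <- butter_coefs(order, band[1] / (fs / 2), "high")
  lp <- butter_coefs(order, band[2] / (fs / 2), "low")
  pad <- ceiling(3 * fs / band[1])
  x <- zero_phase(hp$b, hp$a, x, pad)
  zero_phase(lp$b, lp$a, x, pad = ceiling(3 * fs / band[2]))
}

#' Zero-phase notch (band-stop) filter for line noise
#'
#' @param x numeric signal vector
#' @param band stop-band edges in Hz (default 58-62 Hz)
#' @param fs sampling rate in Hz
#' @param order Butterworth order of the stop-band prototype
#' @return filtered signal, same length as `x`
#' @export
notch_filter <- function(x, band = c(58, 62), fs, order = 4L) {
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2] ||
      band[2] >= fs / 2) {
    stop("band must satisfy 0 < low < high < fs/2 (fs = ", fs, " Hz)")
  }
  bs <- butter_coefs(order, band / (fs / 2), "stop")
  zero_phase(bs$b, bs$a, x, pad = ceiling(3 * fs / band[1]))
}

# apply a single-channel filter across the rows of a channels x samples matrix
filter_rows <- function(x, fun) {
  t(apply(x, 1L, fun))
}

#' Rectify and normalize an EMG signal
#'
#' Full-wave rectification followed by normalization to the peak rectified
#' EMG observed during the maximum-effort shoulder abduction, giving a
#' dimensionless envelope.
#'
#' @param x band-pass filtered EMG signal
#' @param peak_reference peak rectified EMG during maximum SABD (> 0)
#' @return non-negative dimensionless signal
#' @export
emg_envelope <- function(x, peak_reference) {
  if (!is.numeric(peak_reference) || length(peak_reference) != 1L ||
      peak_reference <= 0) {
    stop("peak_reference must be a positive scalar")
  }
  abs(x) / peak_reference
}

#' Cut overlapping fixed-length epochs within trial holds
#'
#' Epochs tile each hold from its start with step `epoch_length - overlap`;
#' the last epoch lies fully inside the hold and epochs never straddle trial
#' boundaries (holds are separated by rest). A 10 s hold cut into 1 s epochs
#' with 250 ms overlap yields 13 epochs. Trials shorter than one epoch
#' contribute nothing and are reported via a message.
#'
#' @param x numeric matrix channels x samples (a vector is treated as one
#'   channel)
#' @param trial_boundaries list of c(start, end) sample indices per hold
#' @param fs sampling rate in Hz
#' @param epoch_length epoch length in seconds
#' @param overlap epoch overlap in seconds
#' @param labels channel labels (defaults to rownames or ch1..chK)
#' @return object of class `bmc_epochs`: list with `data`
#'   [n_epochs x n_channels x n_epoch_samples], `origin` (trial, start
#'   sample per epoch), `fs`, `epoch_length`, `overlap`, `labels`
#' @export
make_epochs <- function(x, trial_boundaries, fs, epoch_length = 1,
                        overlap = 0.25, labels = NULL) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (overlap >= epoch_length) stop("overlap must be smaller than epoch_length")
  if (is.null(labels)) {
    labels <- rownames(x)
    if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(x)))
  }
  len <- round(epoch_length * fs)
  step <- round((epoch_length - overlap) * fs)
  origins <- list()
  for (ti in seq_along(trial_boundaries)) {
    tb <- trial_boundaries[[ti]]
    span <- tb[2] - tb[1] + 1L
    if (span < len) {
      message("trial ", ti, " shorter than one epoch (", span,
              " < ", len, " samples); skipped")
      next
    }
    n_ep <- floor((span - len) / step) + 1L
    starts <- tb[1] + step * (seq_len(n_ep) - 1L)
    origins[[length(origins) + 1L]] <- data.frame(trial = ti, start = starts)
  }
  origin <- if (length(origins)) do.call(rbind, origins) else
    data.frame(trial = integer(), start = integer())
  n_ep <- nrow(origin)
  data <- array(NA_real_, dim = c(n_ep, nrow(x), len))
  for (e in seq_len(n_ep)) {
    idx <- origin$start[e]:(origin$start[e] + len - 1L)
    data[e, , ] <- x[, idx, drop = FALSE]
  }
  structure(
    list(data = data, origin = origin, fs = fs, epoch_length = epoch_length,
         overlap = overlap, labels = labels),
    class = "bmc_epochs"
  )
}

#' Reject epochs exceeding a peak-amplitude limit
#'
#' An epoch is dropped when the absolute amplitude on any channel exceeds
#' `amplitude_limit`. Intended for EEG epochs in microvolts; the default
#' limit in [pipeline_config()] is 100 microvolts. Erroring out when every
#' epoch is rejected protects downstream averaging from empty input.
#'
#' @param e a `bmc_epochs` object
#' @param amplitude_limit positive peak threshold, same units as the data
#' @return `bmc_epochs` with offending epochs removed; the number rejected
#'   is reported via a message when non-zero
#' @export
reject_epochs <- function(e, amplitude_limit) {
  stopifnot(inherits(e, "bmc_epochs"))
  if (!is.numeric(amplitude_limit) || amplitude_limit <= 0) {
    stop("amplitude_limit must be positive")
  }
  n_ep <- dim(e$data)[1]
  peak <- apply(abs(e$data), 1L, max)
  keep <- peak <= amplitude_limit
  if (!any(keep)) {
    stop("all ", n_ep, " epochs exceed the ", amplitude_limit,
         " amplitude limit; review the rejection threshold")
  }
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message("rejected ", n_drop, "/", n_ep, " epochs above amplitude limit ",
            amplitude_limit)
  }
  e$data <- e$data[keep, , , drop = FALSE]
  e$origin <- e$origin[keep, , drop = FALSE]
  rownames(e$origin) <- NULL
  e
}

#' @export
print.bmc_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<bmc_epochs> ", d[1], " epochs x ", d[2], " channels x ", d[3],
      " samples (", x$epoch_length, " s, ", x$overlap, " s overlap, ",
      x$fs, " Hz)\n", sep = "")
  invisible(x)
}

#' Preprocess one recording into analysis-ready EEG and EMG epochs
#'
#' Applies the full conditioning chain on the continuous signals before
#' epoching: EEG band-pass 1-100 Hz plus 58-62 Hz notch; EMG band-pass
#' 20-100 Hz plus notch, full-wave rectification and normalization to the
#' peak rectified EMG of the maximum-effort recording; then cuts 1 s epochs
#' with 250 ms overlap inside each hold and drops EEG epochs above the
#' amplitude limit (the same epochs are dropped from the EMG set to keep
#' the two aligned for cross-spectra). An optional `artifact_hook` runs on
#' the filtered continuous EEG matrix before epoching (pass-through by
#' default); a component-based artifact removal such as ICA can be plugged
#' in there.
#'
#' @param rec a `bmc_recording`
#' @param emg_peak_reference peak rectified EMG during maximum SABD, in the
#'   recording's EMG units (use [emg_peak_from_mvt()] on the MVT recording)
#' @param cfg a [pipeline_config()]
#' @param artifact_hook function(matrix, labels) -> matrix, applied to the
#'   filtered continuous EEG
#' @return list with `eeg` and `emg` as aligned `bmc_epochs`
#' @export
preprocess_recording <- function(rec, emg_peak_reference,
                                 cfg = pipeline_config(),
                                 artifact_hook = NULL) {
  validate_recording(rec)
  fs <- rec$fs
  eeg <- filter_rows(rec$eeg, function(ch) {
    notch_filter(filter_band(ch, cfg$eeg_band, fs), cfg$notch_band, fs)
  })
  if (!is.null(artifact_hook)) eeg <- artifact_hook(eeg, rec$eeg_labels)
  emg <- filter_rows(rec$emg, function(ch) {
    notch_filter(filter_band(ch, cfg$emg_band, fs), cfg$notch_band, fs)
  })
  emg <- t(apply(emg, 1L, emg_envelope, peak_reference = emg_peak_reference))
  eeg_ep <- make_epochs(eeg, rec$trial_boundaries, fs, cfg$epoch_length,
                        cfg$epoch_overlap, labels = rec$eeg_labels)
  emg_ep <- make_epochs(emg, rec$trial_boundaries, fs, cfg$epoch_length,
                        cfg$epoch_overlap, labels = "EMG")
  keep_peak <- apply(abs(eeg_ep$data), 1L, max) <= cfg$amplitude_limit
  if (!any(keep_peak)) {
    stop("all epochs exceed the EEG amplitude limit; review the threshold")
  }
  if (any(!keep_peak)) {
    message("rejected ", sum(!keep_peak), "/", length(keep_peak),
            " epochs above amplitude limit ", cfg$amplitude_limit)
  }
  subset_epochs <- function(e, keep) {
    e$data <- e$data[keep, , , drop = FALSE]
    e$origin <- e$origin[keep, , drop = FALSE]
    rownames(e$origin) <- NULL
    e
  }
  list(eeg = subset_epochs(eeg_ep, keep_peak),
       emg = subset_epochs(emg_ep, keep_peak))
}

#' Peak rectified EMG from a maximum-effort recording
#'
#' Filters the MVT recording's EMG with the standard EMG chain, rectifies
#' it, and returns the global single-sample peak, the normalization
#' reference for [emg_envelope()].
#'
#' @param rec the MVT-condition `bmc_recording`
#' @param cfg a [pipeline_config()]
#' @return positive scalar, same units as the EMG
#' @export
emg_peak_from_mvt <- function(rec, cfg = pipeline_config()) {
  validate_recording(rec)
  f <- notch_filter(filter_band(rec$emg[1L, ], cfg$emg_band, rec$fs),
                    cfg$notch_band, rec$fs)
  max(abs(f))
}
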