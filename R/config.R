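#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis stage with the study
#' defaults: EEG band-pass 1-100 Hz, EMG band-pass 20-100 Hz, notch
#' 58-62 Hz, 1 s epochs with 250 ms overlap (1 Hz spectral grid),
#' EEG frequency range 1-100 Hz and EMG range 20-100 Hz for the frequency
#' pair traversal, and a 0.05 significance level. `nl_index_mode` selects
#' how the N-L index splits electrodes ("literal": linear connectivity
#' summed over the CS set and nonlinear over the IS set; "pooled": both
#' over all 18 sensorimotor electrodes) and `nl_aggregation` whether pair
#' values are summed or averaged.
#'
#' @param eeg_band EEG band-pass edges in Hz
#' @param emg_band EMG band-pass edges in Hz
#' @param notch_band line-noise stop band in Hz
#' @param epoch_length epoch length in seconds
#' @param epoch_overlap epoch overlap in seconds
#' @param eeg_freq_range integer Hz bounds traversed for EEG (f_x)
#' @param emg_freq_range integer Hz bounds traversed for EMG (f_y)
#' @param nl_index_mode "literal" or "pooled"
#' @param nl_aggregation "sum" or "mean"
#' @param taper "rectangular" or "hann"
#' @param amplitude_limit EEG epoch-rejection peak threshold, microvolts
#' @param alpha significance level for all tests
#' @param seed integer seed for stochastic stages
#' @return object of class `bmc_config`
#' @export
pipeline_config <- function(eeg_band = c(1, 100),
                            emg_band = c(20, 100),
                            notch_band = c(58, 62),
                            epoch_length = 1,
                            epoch_overlap = 0.25,
                            eeg_freq_range = c(1L, 100L),
                            emg_freq_range = c(20L, 100L),
                            nl_index_mode = c("literal", "pooled"),
                            nl_aggregation = c("sum", "mean"),
                            taper = c("rectangular", "hann"),
                            amplitude_limit = 100,
                            alpha = 0.05,
                            seed = 1L) {
  nl_index_mode <- match.arg(nl_index_mode)
  nl_aggregation <- match.arg(nl_aggregation)
  taper <- match.arg(taper)
  stopifnot(epoch_overlap < epoch_length, epoch_length > 0,
            alpha > 0, alpha < 1, amplitude_limit > 0)
  rng <- function(r, nm) {
    if (length(r) != 2L || any(r <= 0) || r[1] >= r[2] ||
        any(r != as.integer(r))) {
      stop(nm, " must be positive increasing integer bounds")
    }
    as.integer(r)
  }
  structure(
    list(eeg_band = eeg_band, emg_band = emg_band, notch_band = notch_band,
         epoch_length = epoch_length, epoch_overlap = epoch_overlap,
         eeg_freq_range = rng(eeg_freq_range, "eeg_freq_range"),
         emg_freq_range = rng(emg_freq_range, "emg_freq_range"),
         nl_index_mode = nl_index_mode, nl_aggregation = nl_aggregation,
         taper = taper, amplitude_limit = amplitude_limit,
         alpha = alpha, seed = as.integer(seed)),
    class = "bmc_config"
  )
}

# evaluate expr with a private, restorable RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
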