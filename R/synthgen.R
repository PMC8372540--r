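#' Simulation configuration for the synthetic EEG/EMG/torque generator
#'
#' The generator emulates the statistical structure the analysis assumes: a
#' band-limited cortical source projected to lateralized scalp channels, an
#' EMG driven through a linear (direct, corticospinal-like) pathway and a
#' multi-synaptic (indirect, cascaded static nonlinearity) pathway whose
#' gain scales with the shoulder-abduction load, and torque holds at a
#' fraction of maximum voluntary torque with an involuntary elbow-flexion
#' (flexion synergy) component.
#'
#' Fields accepting a value per task condition (`lateral_ratio`,
#' `load_scaling`, `ef_synergy_ratio`) may be a single number or a named
#' vector with entries `SABD20` / `SABD40`.
#'
#' @param n_trials number of 10 s holds per task condition
#' @param hold_duration hold length, seconds
#' @param fs sampling rate, Hz
#' @param source_band cortical source band, Hz
#' @param lateral_ratio amplitude ratio of the source projection onto the
#'   CS (contralateral/ipsilesional) versus IS hemisphere sensorimotor
#'   electrodes; 1 is symmetric, > 1 CS-dominant
#' @param linear_gain gain of the direct linear pathway (alpha)
#' @param nonlinear_gain gain of the indirect nonlinear pathway (beta)
#' @param synapse_stages cascade depth of the static nonlinearity (k >= 1)
#' @param load_scaling multiplier on `nonlinear_gain` per condition;
#'   the default doubles the indirect drive at the 40% load
#' @param snr_eeg EEG SNR in dB (unit-weight source power over channel
#'   noise power)
#' @param snr_emg EMG SNR in dB (carrier power over sensor noise power)
#' @param modulation_depth depth of the amplitude modulation of the EMG
#'   carrier by the (standardized) pathway drive; the rectified EMG
#'   carries the drive oscillation with this relative amplitude
#' @param ef_synergy_ratio involuntary elbow-flexion torque during holds,
#'   as a fraction of the elbow-flexion MVT
#' @param sabd_mvt maximum voluntary shoulder-abduction torque, N*m
#' @param ef_mvt maximum voluntary elbow-flexion torque, N*m
#' @param gap_duration rest between holds, seconds (holds are analysed,
#'   rests are not, so the simulated rest is kept short)
#' @param seed integer; the generator is deterministic given the seed
#' @return object of class `bmc_simcfg`
#' @export
simulation_config <- function(n_trials = 25L,
                              hold_duration = 10,
                              fs = 2048,
                              source_band = c(8, 30),
                              lateral_ratio = 1,
                              linear_gain = 1,
                              nonlinear_gain = 1,
                              synapse_stages = 3L,
                              load_scaling = c(SABD20 = 1, SABD40 = 2),
                              snr_eeg = 15,
                              snr_emg = 10,
                              modulation_depth = 0.3,
                              ef_synergy_ratio = c(SABD20 = 0.15,
                                                   SABD40 = 0.35),
                              sabd_mvt = 30,
                              ef_mvt = 20,
                              gap_duration = 1,
                              seed = 1L) {
  stopifnot(n_trials >= 1, hold_duration > 0, fs > 0,
            modulation_depth >= 0,
            all(lateral_ratio >= 0), linear_gain >= 0,
            all(nonlinear_gain >= 0), all(load_scaling >= 0),
            all(ef_synergy_ratio >= 0), sabd_mvt > 0, ef_mvt > 0,
            gap_duration >= 0)
  if (synapse_stages < 1 || synapse_stages != as.integer(synapse_stages)) {
    stop("synapse_stages must be an integer >= 1")
  }
  structure(
    list(n_trials = as.integer(n_trials), hold_duration = hold_duration,
         fs = fs, source_band = source_band, lateral_ratio = lateral_ratio,
         linear_gain = linear_gain, nonlinear_gain = nonlinear_gain,
         synapse_stages = as.integer(synapse_stages),
         load_scaling = load_scaling, snr_eeg = snr_eeg, snr_emg = snr_emg,
         modulation_depth = modulation_depth,
         ef_synergy_ratio = ef_synergy_ratio, sabd_mvt = sabd_mvt,
         ef_mvt = ef_mvt, gap_duration = gap_duration,
         seed = as.integer(seed)),
    class = "bmc_simcfg"
  )
}

# per-condition lookup for fields that may be scalars or named vectors
cond_value <- function(x, condition) {
  if (length(x) == 1L && is.null(names(x))) return(unname(x))
  if (condition %in% names(x)) return(unname(x[[condition]]))
  unname(x[[1L]])
}

#' Cascaded static nonlinearity of the indirect pathway
#'
#' Models each synapse of a multi-synaptic pathway as a static memoryless
#' nonlinearity: per stage the signal is mapped through u -> u + c2*u^2 and
#' re-standardized to zero mean and unit variance, so variance stays
#' controlled while harmonic and intermodulation content accumulates with
#' depth. With `c2 = 0` the output is simply the standardized input.
#'
#' @param u numeric signal
#' @param k number of cascaded stages (integer >= 1)
#' @param c2 quadratic coefficient of the per-stage map
#' @return transformed signal, zero mean and unit variance (all-zero for a
#'   constant input)
#' @export
nonlinear_transfer <- function(u, k, c2 = 0.5) {
  if (length(k) != 1L || is.na(k) || k < 1 || k != as.integer(k)) {
    stop("k must be an integer >= 1")
  }
  standardize <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }
  u <- standardize(u)
  for (i in seq_len(k)) {
    u <- standardize(u + c2 * u^2)
  }
  u
}

# unit-variance Gaussian noise band-limited by the standard zero-phase chain
band_noise <- function(n, band, fs) {
  x <- filter_band(stats::rnorm(n), band, fs)
  x / stats::sd(x)
}

# unit-variance 1/f ("pink") noise via spectral shaping
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)           # two-sided frequency index
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

# circular delay keeps length and stationarity
delay_signal <- function(x, samples) {
  n <- length(x)
  s <- samples %% n
  if (s == 0L) return(x)
  c(x[(n - s + 1L):n], x[1L:(n - s)])
}

#' Simulate one subject x condition recording
#'
#' Generates a [recording()] with `n_trials` holds. EEG channel i is
#' w_i * c(t) + pink noise, where c(t) is a band-limited Gaussian cortical
#' source and the hemispheric projection weights implement `lateral_ratio`
#' (CS sensorimotor electrodes weighted `lateral_ratio`, IS weighted 1,
#' non-sensorimotor sites 0.3). The EMG is a broadband carrier
#' amplitude-modulated by the pathway drive
#' alpha * lin(t) + beta(condition) * N_k(nl(t)) plus white sensor noise,
#' where N_k is [nonlinear_transfer()] with `synapse_stages` stages and the
#' two pathway inputs are delayed copies of the source (10 ms direct, 30 ms
#' indirect). Torque holds sit at the condition's target fraction of the
#' SABD MVT with slow fluctuation, and the elbow-flexion row carries the
#' involuntary synergy torque `ef_synergy_ratio * ef_mvt`. The `MVT`
#' condition produces three maximal efforts (3 s holds) on both torque
#' axes with a stronger EMG carrier, used for MVT estimation and EMG
#' normalization. Deterministic given `cfg$seed`.
#'
#' @param cfg a [simulation_config()]
#' @param group "stroke" or "control"
#' @param condition "SABD20", "SABD40" or "MVT"
#' @param subject_id identifier stored in the recording
#' @param tested_arm tested (for stroke: paretic) arm
#' @param lesioned_hemisphere lesion side for stroke ("none" for controls;
#'   defaults to the hemisphere contralateral to the tested arm)
#' @return a validated `bmc_recording`
#' @export
simulate_subject <- function(cfg, group = c("stroke", "control"),
                             condition = c("SABD20", "SABD40", "MVT"),
                             subject_id = "S01",
                             tested_arm = "left",
                             lesioned_hemisphere = NULL) {
  group <- match.arg(group)
  condition <- match.arg(condition)
  tested_arm <- match.arg(tested_arm, c("left", "right"))
  contralateral <- if (tested_arm == "right") "left" else "right"
  if (is.null(lesioned_hemisphere)) {
    lesioned_hemisphere <- if (group == "stroke") contralateral else "none"
  }
  if (group == "stroke" && lesioned_hemisphere == tested_arm) {
    stop("invalid combination: the paretic (tested) arm must be ",
         "contralateral to the lesion")
  }
  if (group == "control" && lesioned_hemisphere != "none") {
    stop("invalid combination: controls have no lesion")
  }

  fs <- cfg$fs
  is_mvt <- condition == "MVT"
  n_tr <- if (is_mvt) 3L else cfg$n_trials
  hold <- if (is_mvt) min(3, cfg$hold_duration) else cfg$hold_duration
  gap <- cfg$gap_duration
  hold_n <- round(hold * fs)
  gap_n <- round(gap * fs)
  n <- gap_n + n_tr * (hold_n + gap_n)
  starts <- gap_n + (seq_len(n_tr) - 1L) * (hold_n + gap_n) + 1L
  trial_boundaries <- lapply(starts, function(s) c(s, s + hold_n - 1L))

  labels <- default_montage()
  lambda <- cond_value(cfg$lateral_ratio, condition)
  beta <- cfg$nonlinear_gain *
    (if (is_mvt) 1 else cond_value(cfg$load_scaling, condition))
  target_frac <- switch(condition, SABD20 = 0.2, SABD40 = 0.4, MVT = 1)
  ef_frac <- if (is_mvt) NA else cond_value(cfg$ef_synergy_ratio, condition)

  with_seed(cfg$seed, {
    src <- band_noise(n, cfg$source_band, fs)

    # EEG: lateralized projection + pink channel noise (microvolts)
    source_rms <- 10
    cs_side <- if (group == "stroke") lesioned_hemisphere else contralateral
    w <- rep(0.3, length(labels))
    w[labels %in% sensorimotor_labels(cs_side)] <- lambda
    w[labels %in% sensorimotor_labels(
      if (cs_side == "left") "right" else "left")] <- 1
    noise_sd <- source_rms * 10^(-cfg$snr_eeg / 20)
    eeg <- matrix(0, length(labels), n)
    for (i in seq_along(labels)) {
      eeg[i, ] <- w[i] * source_rms * src + noise_sd * pink_noise(n)
    }

    # EMG: amplitude-modulated broadband carrier + white noise (millivolts)
    d_lin <- delay_signal(src, round(0.010 * fs))
    v <- delay_signal(src, round(0.030 * fs))
    d_nl <- nonlinear_transfer(v, cfg$synapse_stages)
    # the static cascade retains a component proportional to its input
    # (Bussgang: for a Gaussian input the cross-covariance of g(v) with v
    # is a constant multiple of the autocovariance), so project it out:
    # the indirect drive then carries only cross-frequency structure and
    # the linear/nonlinear couplings are controlled solely by alpha/beta
    rho <- stats::cov(d_nl, v) / stats::var(v)
    d_nl <- d_nl - rho * v
    nsd <- stats::sd(d_nl)
    if (nsd > 0) d_nl <- d_nl / nsd
    drive <- cfg$linear_gain * d_lin + beta * d_nl
    dsd <- stats::sd(drive)
    if (dsd > 0) drive <- drive / dsd
    carrier_band <- c(20, min(400, 0.45 * fs))
    carrier <- band_noise(n, carrier_band, fs)
    carrier_amp <- if (is_mvt) 1.25 else 0.5
    depth <- cfg$modulation_depth
    emg_noise_sd <- carrier_amp * 10^(-cfg$snr_emg / 20)
    emg <- carrier_amp * carrier * (1 + depth * drive) +
      emg_noise_sd * stats::rnorm(n)
    emg <- matrix(emg, nrow = 1L)

    # torque: holds at target with slow fluctuation; EF synergy component
    slow <- band_noise(n, c(0.2, 1.5), fs)
    slow2 <- band_noise(n, c(0.2, 1.5), fs)
    sabd <- 0.005 * cfg$sabd_mvt * slow
    ef <- 0.005 * cfg$ef_mvt * slow2
    effort <- stats::rnorm(n_tr, mean = 1, sd = 0.02)
    for (ti in seq_len(n_tr)) {
      idx <- trial_boundaries[[ti]][1]:trial_boundaries[[ti]][2]
      sabd[idx] <- target_frac * cfg$sabd_mvt * effort[ti] +
        0.02 * cfg$sabd_mvt * slow[idx]
      ef[idx] <- if (is_mvt) {
        cfg$ef_mvt * effort[ti] + 0.01 * cfg$ef_mvt * slow2[idx]
      } else {
        ef_frac * cfg$ef_mvt + 0.01 * cfg$ef_mvt * slow2[idx]
      }
    }
    torque <- rbind(sabd, ef)
    rownames(torque) <- NULL

    recording(eeg = eeg, emg = emg, torque = torque, fs = fs,
              eeg_labels = labels, subject_id = subject_id, group = group,
              condition = condition, tested_arm = tested_arm,
              lesioned_hemisphere = lesioned_hemisphere,
              trial_boundaries = trial_boundaries)
  })
}

#' Group-level generator presets
#'
#' Study conditions for the simulated cohort: stroke subjects rely more on
#' the indirect nonlinear pathway (smaller linear gain, larger nonlinear
#' gain), show contralesional source dominance that deepens with load
#' (lateral_ratio < 1, smaller at 40%), and a strong load-dependent
#' flexion-synergy ratio; controls are the mirror image (linear-dominant,
#' contralateral source dominance, negligible synergy torque).
#'
#' @param group "stroke" or "control"
#' @return named list of [simulation_config()] overrides
#' @export
group_preset <- function(group = c("stroke", "control")) {
  group <- match.arg(group)
  if (group == "stroke") {
    list(linear_gain = 0.4, nonlinear_gain = 1.2,
         lateral_ratio = c(SABD20 = 0.85, SABD40 = 0.75),
         ef_synergy_ratio = c(SABD20 = 0.15, SABD40 = 0.35))
  } else {
    list(linear_gain = 1.2, nonlinear_gain = 0.15,
         lateral_ratio = c(SABD20 = 1.3, SABD40 = 1.3),
         ef_synergy_ratio = c(SABD20 = 0.02, SABD40 = 0.03))
  }
}

#' Simulate a two-group cohort
#'
#' Generates `n_per_group` stroke and control subjects, each with an MVT
#' recording and both task conditions, using [group_preset()] on top of a
#' shared base configuration. Tested arms follow the 3:1 left:right split
#' of paretic arms typical of a small hemiparetic cohort. Per-recording
#' seeds are derived deterministically from `seed`.
#'
#' @param n_per_group subjects per group
#' @param base_cfg a [simulation_config()] carrying the shared parameters
#'   (trial count, sampling rate, SNRs, ...)
#' @param seed master seed for the cohort
#' @return nested list: `subjects[[id]]` with `group`, `tested_arm`,
#'   `lesioned_hemisphere` and `recordings` (MVT, SABD20, SABD40)
#' @export
simulate_cohort <- function(n_per_group = 8L,
                            base_cfg = simulation_config(),
                            seed = base_cfg$seed) {
  subjects <- list()
  sidx <- 0L
  for (group in c("stroke", "control")) {
    preset <- group_preset(group)
    for (i in seq_len(n_per_group)) {
      sidx <- sidx + 1L
      id <- sprintf("%s%02d", if (group == "stroke") "STR" else "CTL", i)
      arm <- if (i %% 4L == 0L) "right" else "left"
      cfg_i <- base_cfg
      cfg_i[names(preset)] <- preset
      recs <- list()
      for (ci in seq_along(c("MVT", "SABD20", "SABD40"))) {
        cond <- c("MVT", "SABD20", "SABD40")[ci]
        cfg_i$seed <- (seed + 101L * sidx + 7L * ci) %% .Machine$integer.max
        recs[[cond]] <- simulate_subject(cfg_i, group, cond, subject_id = id,
                                         tested_arm = arm)
      }
      subjects[[id]] <- list(id = id, group = group, tested_arm = arm,
                             lesioned_hemisphere =
                               recs$SABD20$lesioned_hemisphere,
                             recordings = recs)
    }
  }
  subjects
}
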