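test_that("the cascade creates harmonic content a linear map lacks", {
  fs <- 256
  t <- seq_len(4 * fs) / fs
  u <- cos(2 * pi * 10 * t)
  spec_power <- function(x, f) {
    co <- stats::fft(x - mean(x)) / length(x)
    Mod(co[f * 4 + 1L])^2       # 0.25 Hz grid for a 4 s window
  }
  y1 <- nonlinear_transfer(u, 1)
  expect_gt(spec_power(y1, 10), 1e-4)   # fundamental survives
  expect_gt(spec_power(y1, 20), 1e-4)   # second harmonic appears
  # c2 = 0 is the linear limit: standardized input, no harmonic
  y0 <- nonlinear_transfer(u, 3, c2 = 0)
  expect_equal(y0, (u - mean(u)) / sd(u), tolerance = 1e-12)
  expect_lt(spec_power(y0, 20), 1e-20)
  # second-harmonic power is non-decreasing in cascade depth
  p2 <- vapply(1:3, function(k) spec_power(nonlinear_transfer(u, k), 20),
               numeric(1))
  expect_true(all(diff(p2) >= -1e-12))
  # contract checks
  expect_error(nonlinear_transfer(u, 0), "k must be")
  expect_error(nonlinear_transfer(u, 1.5), "k must be")
  expect_equal(nonlinear_transfer(rep(2, 100), 2), rep(0, 100))
})

test_that("the generator is deterministic given its seed", {
  cfg <- quick_cfg(n_trials = 1L, seed = 99L)
  r1 <- simulate_subject(cfg, "stroke", "SABD40")
  r2 <- simulate_subject(cfg, "stroke", "SABD40")
  expect_identical(r1, r2)
  cfg2 <- quick_cfg(n_trials = 1L, seed = 100L)
  r3 <- simulate_subject(cfg2, "stroke", "SABD40")
  expect_false(identical(r1$eeg, r3$eeg))
})

test_that("recordings carry the protocol structure", {
  cfg <- quick_cfg(n_trials = 2L, seed = 5L)
  rec <- simulate_subject(cfg, "stroke", "SABD20", subject_id = "S9",
                          tested_arm = "left")
  expect_s3_class(rec, "bmc_recording")
  expect_length(rec$eeg_labels, 32L)
  expect_true(all(sensorimotor_labels("both") %in% rec$eeg_labels))
  expect_length(rec$trial_boundaries, 2L)
  expect_equal(rec$lesioned_hemisphere, "right")  # contralateral to paresis
  for (tb in rec$trial_boundaries) {
    expect_equal(tb[2] - tb[1] + 1L, round(cfg$hold_duration * cfg$fs))
  }
  # SABD torque holds near 20% of MVT, elbow flexion near the synergy ratio
  idx <- unlist(lapply(rec$trial_boundaries, function(tb) tb[1]:tb[2]))
  expect_equal(mean(rec$torque[1, idx]) / cfg$sabd_mvt, 0.2,
               tolerance = 0.05)
  expect_equal(mean(rec$torque[2, idx]) / cfg$ef_mvt,
               unname(cfg$ef_synergy_ratio["SABD20"]), tolerance = 0.05)
  # invalid metadata combinations are refused
  expect_error(simulate_subject(cfg, "stroke", "SABD20",
                                tested_arm = "left",
                                lesioned_hemisphere = "left"),
               "contralateral")
  expect_error(simulate_subject(cfg, "control", "SABD20",
                                lesioned_hemisphere = "left"), "lesion")
})

test_that("MVT recordings hold three maximal efforts", {
  cfg <- quick_cfg(seed = 21L)
  rec <- simulate_subject(cfg, "control", "MVT")
  expect_length(rec$trial_boundaries, 3L)
  m <- mvt_from_recording(rec)
  expect_equal(m$sabd, cfg$sabd_mvt, tolerance = 0.15)
  expect_equal(m$ef, cfg$ef_mvt, tolerance = 0.15)
})

test_that("channel powers recover the configured lateral ratio", {
  for (lam in c(0.5, 2)) {
    cfg <- quick_cfg(n_trials = 4L, seed = 31L, lateral_ratio = lam)
    rec <- simulate_subject(cfg, "control", "SABD20", tested_arm = "right")
    pp <- preprocess_recording(rec, 1, pipeline_config())
    roles <- assign_laterality(rec$eeg_labels, "right", "none", "control")
    li <- laterality_index(channel_power(pp$eeg), roles)
    expect_equal(li, (lam - 1) / (lam + 1), tolerance = 0.05)
  }
})

test_that("nonlinear 1:2 coupling strengthens with the indirect-pathway gain", {
  # high-SNR regime (30 dB, deepened drive modulation) with ~325 epochs so
  # the 1:2 lift resolves above the independence-null bias of the
  # estimator; common random numbers across the sweep
  mean12 <- vapply(c(0, 0.5, 1, 2), function(beta) {
    cfg <- quick_cfg(n_trials = 25L, seed = 31L, nonlinear_gain = beta,
                     snr_eeg = 30, snr_emg = 30, modulation_depth = 0.6)
    rec <- simulate_subject(cfg, "control", "SABD20")
    pp <- preprocess_recording(rec, 1, pipeline_config())
    sx <- fourier_coefficients(select_channels(pp$eeg,
                                               sensorimotor_labels("both")))
    sy <- fourier_coefficients(pp$emg)
    pairs <- enumerate_pairs()
    p12 <- pairs[pairs$n == 1L & pairs$m == 2L &
                   pairs$f_x >= 10L & pairs$f_x <= 30L, ]
    cm <- csc_map(sx, sy, p12)
    mean(cm$values)
  }, numeric(1))
  expect_true(all(diff(mean12) > 0))
})

test_that("with no nonlinear gain, iso-frequency coupling matches the null", {
  # alpha = 0: the orthogonalized indirect drive must leave linear CSC at
  # chance level inside the source band
  cfg <- quick_cfg(n_trials = 8L, seed = 13L, linear_gain = 0,
                   nonlinear_gain = 1, snr_eeg = 25, snr_emg = 25)
  rec <- simulate_subject(cfg, "control", "SABD20")
  mv <- simulate_subject(cfg, "control", "MVT")
  pp <- preprocess_recording(rec, emg_peak_from_mvt(mv), pipeline_config())
  sx <- fourier_coefficients(select_channels(pp$eeg, "C3"))
  sy <- fourier_coefficients(pp$emg)
  pairs <- enumerate_pairs()
  lin <- pairs[pairs$kind == "linear" & pairs$f_x >= 20 & pairs$f_x <= 30, ]
  obs <- csc_map(sx, sy, lin)$values[1, ]
  # permutation null for one representative in-band pair
  pn <- permutation_null(sx, sy, lin[3, ], n_perm = 200, seed = 4L)
  expect_lt(mean(obs), unname(pn$percentiles["95%"]))
})

test_that("cohort simulation produces both groups with all conditions", {
  cfg <- quick_cfg(n_trials = 1L, seed = 8L)
  coh <- simulate_cohort(2L, cfg, seed = 8L)
  expect_length(coh, 4L)
  groups <- vapply(coh, `[[`, character(1), "group")
  expect_equal(sum(groups == "stroke"), 2L)
  expect_named(coh[["STR01"]]$recordings, c("MVT", "SABD20", "SABD40"))
  expect_equal(coh[["CTL02"]]$recordings$SABD40$condition, "SABD40")
  expect_equal(coh[["STR01"]]$recordings$SABD20$group, "stroke")
})
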