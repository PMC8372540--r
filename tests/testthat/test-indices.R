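fs <- 128

test_that("channel power is the epoch-averaged RMS amplitude", {
  d <- array(0, dim = c(2, 2, fs))
  d[, 1, ] <- 3                           # constant channel
  t <- seq_len(fs) / fs
  d[1, 2, ] <- sin(2 * pi * 8 * t)        # unit sinusoid
  d[2, 2, ] <- sin(2 * pi * 8 * t)
  e <- epochs_from_array(d, fs, labels = c("A1", "A2"))
  p <- channel_power(e)
  expect_equal(unname(p["A1"]), 3)
  expect_equal(unname(p["A2"]), 1 / sqrt(2), tolerance = 1e-12)
  # homogeneity: doubling samples doubles power
  e2 <- e
  e2$data <- 2 * e2$data
  expect_equal(channel_power(e2), 2 * p)
  e0 <- e
  e0$data <- e0$data[0, , , drop = FALSE]
  expect_error(channel_power(e0), "epoch")
})

test_that("the Laterality Index follows its defining arithmetic", {
  roles <- assign_laterality(default_montage(), "right", "none", "control")
  mk <- function(cs, is_) {
    p <- c(rep(cs, 9), rep(is_, 9))
    names(p) <- c(roles$cs_set, roles$is_set)
    p
  }
  expect_equal(laterality_index(mk(1, 1), roles), 0)
  expect_equal(laterality_index(mk(1, 0), roles), 1)
  expect_equal(laterality_index(mk(2, 1), roles), 1 / 3)
  expect_error(laterality_index(mk(1, 1)[-1], roles),
               roles$cs_set[1])
})

# minimal connectivity map with controlled linear/nonlinear values
toy_cmap <- function(lin_val, nl_val, labels = sensorimotor_labels("both")) {
  pairs <- data.frame(f_x = c(20L, 10L), f_y = c(20L, 20L),
                      n = c(1L, 1L), m = c(1L, 2L),
                      kind = c("linear", "nonlinear"))
  structure(
    list(values = cbind(rep(lin_val, length(labels)),
                        rep(nl_val, length(labels))),
         pairs = pairs, labels = labels, L = 10L),
    class = "bmc_cmap"
  )
}

test_that("the N-L index contrasts nonlinear against linear connectivity", {
  roles <- assign_laterality(default_montage(), "right", "none", "control")
  expect_equal(nl_index(toy_cmap(0.2, 0.2), roles), 0)
  expect_equal(nl_index(toy_cmap(0, 0.4), roles), 1)
  expect_equal(nl_index(toy_cmap(0.4, 0), roles), -1)
  expect_equal(nl_index(toy_cmap(0.1, 0.3), roles), 0.5)
  # pooled mode and mean aggregation agree on this symmetric map
  expect_equal(nl_index(toy_cmap(0.1, 0.3), roles, "pooled", "mean"), 0.5)
  expect_true(is.na(nl_index(toy_cmap(0, 0), roles)))
  small <- toy_cmap(0.1, 0.3, labels = c("C3", "C4"))
  expect_error(nl_index(small, roles), "missing channels")
})

test_that("LI and N-L are invariant to global signal rescaling", {
  cfg <- quick_cfg(n_trials = 2L, seed = 41L, lateral_ratio = 1.5)
  rec <- simulate_subject(cfg, "control", "SABD20")
  roles <- assign_laterality(rec$eeg_labels, rec$tested_arm, "none",
                             "control")
  # generous amplitude limit so the same epochs survive at both scales
  pcfg <- pipeline_config(amplitude_limit = 1e6)
  compute <- function(r) {
    pp <- preprocess_recording(r, 1, pcfg)
    sx <- fourier_coefficients(select_channels(pp$eeg,
                                               sensorimotor_labels("both")))
    sy <- fourier_coefficients(pp$emg)
    cm <- csc_map(sx, sy, enumerate_pairs(c(20L, 30L), c(20L, 30L)))
    c(li = laterality_index(channel_power(pp$eeg), roles),
      nl = nl_index(cm, roles))
  }
  scaled <- rec
  scaled$eeg <- 3 * scaled$eeg
  scaled$emg <- 3 * scaled$emg
  expect_equal(compute(scaled), compute(rec), tolerance = 1e-8)
})

test_that("the MVT consistency rule accepts <= 10% spread and flags more", {
  expect_equal(mvt(c(100, 105, 95)), 100)       # spread exactly 10%
  expect_warning(m <- mvt(c(100, 120, 95)), "inconsistent")
  expect_true(is.na(m))
  expect_equal(mvt(c(50, 50, 50)), 50)
  expect_error(mvt(c(100, 105)), "exactly 3")
  expect_error(mvt(c(100, -5, 100)), "positive")
})

test_that("the flexion-synergy ratio normalizes hold-mean EF torque", {
  tb <- list(c(1, 100), c(201, 300))
  ef <- rep(0, 300)
  expect_equal(flexion_synergy(ef, tb, 20), 0)
  ef2 <- rep(20, 300)
  expect_equal(flexion_synergy(ef2, tb, 20), 1)
  ef3 <- c(rep(4, 100), rep(99, 100), rep(4, 100))  # rest ignored
  expect_equal(flexion_synergy(ef3, tb, 20), 0.2)
  expect_error(flexion_synergy(ef, list(), 20), "hold")
  expect_error(flexion_synergy(ef, tb, 0), "positive")
})

test_that("the generator's synergy ratio is recovered from its torque", {
  cfg <- quick_cfg(n_trials = 2L, seed = 12L,
                   ef_synergy_ratio = c(SABD20 = 0.2, SABD40 = 0.4))
  rec <- simulate_subject(cfg, "stroke", "SABD20")
  fsr <- flexion_synergy(rec$torque[2, ], rec$trial_boundaries, cfg$ef_mvt)
  expect_equal(fsr, 0.2, tolerance = 0.02)
})
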