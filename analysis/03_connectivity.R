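#!/usr/bin/env Rscript

# Step 3 — cross-spectral connectivity.
#
# For every subject x task condition, computes the CSC map over the 18
# sensorimotor electrodes and the full frequency-pair traversal
# (f_x 1-100 Hz, f_y 20-100 Hz, iso-frequency pairs plus all pairs with a
# common factor > 1). Writes the long-format connectivity table and caches
# the maps for the index step.

suppressMessages(library(bmconn))

manifest <- read.delim("results/manifest.tsv")
cfg <- pipeline_config()
dir.create("results/connectivity", showWarnings = FALSE)
dir.create("results/cache", showWarnings = FALSE)

pairs <- enumerate_pairs(cfg$eeg_freq_range, cfg$emg_freq_range)
message(nrow(pairs), " frequency pairs (",
        sum(pairs$kind == "linear"), " linear, ",
        sum(pairs$kind == "nonlinear"), " nonlinear)")

for (id in unique(manifest$subject)) {
  sub <- manifest[manifest$subject == id, ]
  recs <- lapply(setNames(sub$file, sub$condition), function(f) {
    read_recording(file.path("results/recordings", f))
  })
  peak <- emg_peak_from_mvt(recs$MVT, cfg)
  for (cond in c("SABD20", "SABD40")) {
    pp <- preprocess_recording(recs[[cond]], peak, cfg)
    sx <- fourier_coefficients(
      select_channels(pp$eeg, sensorimotor_labels("both")), cfg$taper)
    sy <- fourier_coefficients(pp$emg, cfg$taper)
    cm <- csc_map(sx, sy, pairs)
    tab <- connectivity_table(cm, id, sub$group[1], cond)
    write.table(tab,
                file.path("results/connectivity",
                          sprintf("%s_%s.tsv", id, cond)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    saveRDS(list(cmap = cm, power = channel_power(pp$eeg),
                 n_epochs = dim(pp$eeg$data)[1]),
            file.path("results/cache", sprintf("%s_%s.rds", id, cond)))
    message(id, " ", cond, ": peak linear CSC ",
            signif(max(cm$values[, cm$pairs$kind == "linear"]), 3),
            ", peak nonlinear CSC ",
            signif(max(cm$values[, cm$pairs$kind == "nonlinear"]), 3))
  }
}
message("long-format tables under results/connectivity/")
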