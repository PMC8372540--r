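#!/usr/bin/env Rscript

# Step 4 — summary indices.
#
# Laterality Index of sensorimotor EEG power, N-L (nonlinear-over-linear)
# index of the CSC map, and the flexion-synergy ratio (hold-mean
# involuntary elbow-flexion torque over the elbow-flexion MVT). The N-L
# index is reported under both electrode-split modes and both
# aggregations, since the raw sum is mechanically inflated by the large
# nonlinear pair set.

suppressMessages(library(bmconn))

manifest <- read.delim("results/manifest.tsv")
cfg <- pipeline_config()

rows <- list()
for (id in unique(manifest$subject)) {
  sub <- manifest[manifest$subject == id, ]
  recs <- lapply(setNames(sub$file, sub$condition), function(f) {
    read_recording(file.path("results/recordings", f))
  })
  mvts <- mvt_from_recording(recs$MVT)
  roles <- assign_laterality(recs$SABD20$eeg_labels, recs$SABD20$tested_arm,
                             recs$SABD20$lesioned_hemisphere,
                             recs$SABD20$group)
  for (cond in c("SABD20", "SABD40")) {
    cache <- readRDS(file.path("results/cache",
                               sprintf("%s_%s.rds", id, cond)))
    rows[[paste(id, cond)]] <- data.frame(
      subject = id, group = sub$group[1], condition = cond,
      li = laterality_index(cache$power, roles),
      nl = nl_index(cache$cmap, roles, cfg$nl_index_mode,
                    cfg$nl_aggregation),
      nl_literal_mean = nl_index(cache$cmap, roles, "literal", "mean"),
      nl_pooled_mean = nl_index(cache$cmap, roles, "pooled", "mean"),
      nl_pooled_sum = nl_index(cache$cmap, roles, "pooled", "sum"),
      fs_ratio = flexion_synergy(recs[[cond]]$torque[2, ],
                                 recs[[cond]]$trial_boundaries, mvts$ef),
      n_epochs = cache$n_epochs
    )
  }
}
indices <- do.call(rbind, c(rows, make.row.names = FALSE))
write.table(indices, "results/indices.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

agg <- aggregate(cbind(li, nl, fs_ratio) ~ group + condition, indices, mean)
message("group means (default N-L mode = ", cfg$nl_index_mode, "/",
        cfg$nl_aggregation, "):")
print(agg, digits = 3)
message("index table: results/indices.tsv")
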