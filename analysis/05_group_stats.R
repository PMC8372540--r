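#!/usr/bin/env Rscript

# Step 5 — group statistics and figures.
#
# Within-group paired load comparisons (one-tailed for stroke with the
# hypothesized directions, two-tailed for controls) and one-tailed
# two-sample stroke-vs-control comparisons at each load, gated by
# Shapiro-Wilk and Levene checks with Welch fallback for unpaired
# heteroscedastic samples. Box plots of the three indices by group and
# load accompany the tables.

suppressMessages(library(bmconn))

indices <- read.delim("results/indices.tsv")
st <- cohort_stats(indices, alpha = 0.05)

write.table(st$table, "results/stats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(
  lapply(st$reports, function(r) {
    unclass(r)[c("test", "statistic", "df", "p", "tail", "paired",
                 "decision")]
  }),
  "results/stats.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

dir.create("results/figures", showWarnings = FALSE)
pdf("results/figures/indices_by_group.pdf", width = 9, height = 3.2)
op <- par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
for (m in c("li", "nl", "fs_ratio")) {
  boxplot(indices[[m]] ~ interaction(indices$condition, indices$group),
          ylab = m, xlab = "", las = 2, cex.axis = 0.8,
          col = rep(c("#9ecae1", "#fc9272"), each = 2))
  abline(h = 0, lty = 3)
}
par(op)
dev.off()

sig <- st$table[st$table$significant, c("measure", "comparison", "p")]
message("significant comparisons at alpha = 0.05:")
print(sig, digits = 3, row.names = FALSE)
message("tables: results/stats.tsv, results/stats.json; figure: ",
        "results/figures/indices_by_group.pdf")
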