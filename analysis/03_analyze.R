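#!/usr/bin/env Rscript
# Step 3: descriptive and inferential analysis of the index table.
#
# One 2x2 within-subject repeated-measures ANOVA (time x limb) per band x
# measure (four in total), Bonferroni-adjusted pairwise contrasts among the
# four design cells, Shapiro-Wilk screening, and the publication-style
# descriptives table. Everything is written under results/.

suppressPackageStartupMessages(library(tremorband))

if (!file.exists("results/indices.csv")) {
  stop("run analysis/02_extract.R first (no results/indices.csv)")
}
indices <- data.table::fread("results/indices.csv", data.table = FALSE)

res <- run_analyze(indices)

anova_tbl <- do.call(rbind, lapply(names(res$anova), function(k) {
  cbind(analysis = k, as.data.frame(res$anova[[k]]))
}))
pairwise_tbl <- do.call(rbind, lapply(names(res$pairwise), function(k) {
  cbind(analysis = k, as.data.frame(res$pairwise[[k]]))
}))
shapiro_tbl <- do.call(rbind, lapply(names(res$shapiro), function(k) {
  cbind(analysis = k, as.data.frame(res$shapiro[[k]]))
}))

data.table::fwrite(anova_tbl, "results/anova.csv")
data.table::fwrite(pairwise_tbl, "results/pairwise.csv")
data.table::fwrite(shapiro_tbl, "results/shapiro.csv")
data.table::fwrite(res$descriptives, "results/descriptives.csv")
writeLines(res$report, "results/report.txt")

cat(res$report, sep = "\n")
cat("\nTables written: results/{anova,pairwise,shapiro,descriptives}.csv and results/report.txt\n")
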