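#!/usr/bin/env Rscript
# Stage 5: bound/input densitometry statistics on the stage-1 replicate
# table: per-condition mean ratio with SEM, and pairwise pooled-variance
# Student's t tests (two-sided; no multiple-testing correction, matching
# the analysis this mirrors).

suppressPackageStartupMessages(library(xlmapr))
simdir <- "results/sim"
out <- "results/coip"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tb <- read_densitometry_tsv(file.path(simdir, "densitometry.tsv"))
res <- coip_analysis(tb)
write.table(res$summaries, file.path(out, "summaries.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$tests, file.path(out, "tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("bound/input summaries (mean +/- SEM):\n")
for (i in seq_len(nrow(res$summaries)))
  cat(sprintf("  %s + %s: %.2f +/- %.2f (n = %d)\n",
              res$summaries$construct[i], res$summaries$partner[i],
              res$summaries$mean_ratio[i], res$summaries$sem[i],
              res$summaries$n[i]))
cat("pairwise pooled-variance t tests:\n")
for (i in seq_len(nrow(res$tests)))
  cat(sprintf("  %s vs %s: t = %.3f, df = %d, p = %.3f\n",
              res$tests$groupA[i], res$tests$groupB[i], res$tests$t[i],
              res$tests$df[i], res$tests$p[i]))
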