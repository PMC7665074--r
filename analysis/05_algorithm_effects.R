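#!/usr/bin/env Rscript
# Which workflow step drives pipeline performance? Kruskal-Wallis + Dunn
# post-hoc (BH-adjusted) on the 1-100-scaled overall scores grouped by the
# algorithm used at each step, before and after excluding unnormalized
# ('raw') pipelines.

suppressPackageStartupMessages(library(rgeqbench))

manifest <- read_manifest("results/data/manifest.tsv")
tab <- read.delim("results/pipeline_scores.tsv")
scores <- data.frame(pipeline_id = tab$pipeline_id,
                     median_precision = tab$median_precision,
                     median_accuracy = tab$median_accuracy,
                     overall = tab$median_overall_precision_and_accuracy,
                     rank = tab$ranking)

rows <- list()
for (st in c("trimmer", "aligner", "counter", "normalization")) {
  res <- compare_step(scores, manifest, st,
                      exclude_normalizations =
                        if (st == "normalization") NULL else "raw")
  for (pass in c("all", "filtered")) {
    r <- res[[pass]]
    if (is.null(r)) next
    cat(sprintf("%-14s (%s): KW H = %6.2f, p = %.4g\n", st, pass, r$H, r$p))
    rows[[length(rows) + 1]] <- data.frame(step = st, pass = pass,
                                           H = r$H, kw_p = r$p, r$pairwise)
  }
}
out <- do.call(rbind, rows)
write.table(out, "results/algorithm_effects.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- out[out$p_adj < 0.05, ]
cat(sprintf("\n%d of %d pairwise Dunn comparisons significant at FDR < 0.05\n",
            nrow(sig), nrow(out)))
if (nrow(sig)) print(sig[, c("step", "pass", "group_i", "group_j", "z",
                             "p_adj")], row.names = FALSE)
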