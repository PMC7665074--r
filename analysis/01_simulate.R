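#!/usr/bin/env Rscript
# Simulate the study inputs: a factorial manifest of quantification
# pipelines (48 here: 3 trimmers x 2 aligners x 2 counters x 4
# normalizations, one of them a deliberately unnormalized 'raw' label) and
# 1000 genes over the 18-sample two-cell-line design. The paired qRT-PCR
# Ct table is generated in 02 once the candidate genes are known.

suppressPackageStartupMessages(library(rgeqbench))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
seed <- 20260927L

design <- sample_sheet()
manifest <- pipeline_manifest(
  aligners = c("STAR", "TopHat2"),
  counters = c("HTSeq_Union", "Cufflinks"),
  normalizations = c("TMM", "RLE", "TPM", "raw"),
  seed = seed)
truth <- generate_truth(1000, design, de_fraction = 0.15, effect_size = 2,
                        seed = seed)
panels <- generate_panels(truth, manifest, seed = seed)

write_manifest(manifest, "results/data/manifest.tsv")
write_truth(truth, "results/data/truth.json")
dir.create("results/data/panels", showWarnings = FALSE)
for (p in panels)
  write_panel(p, file.path("results/data/panels",
                           paste0(p$pipeline_id, ".tsv")))

cat(sprintf("simulated %d pipelines x %d genes x %d samples\n",
            nrow(manifest), length(truth$gene_ids), nrow(design)))
cat(sprintf("planted stable gene: %s; planted DE fraction: 0.15\n",
            truth$stable_gene))
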