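#!/usr/bin/env Rscript
# Housekeeping-gene filtering and qRT-PCR candidate selection: keep genes
# with >= 4 expression units in all six control samples of every pipeline,
# then pick 10 highest-CoV + 10 lowest-CoV + 10 random mid-stratum genes
# plus 2 designated controls (32 candidates). The qRT-PCR Ct table is then
# generated for the candidates (plus the planted stable gene, so stability
# recovery can be assessed).

suppressPackageStartupMessages(library(rgeqbench))
seed <- 20260927L

design <- sample_sheet()
manifest <- read_manifest("results/data/manifest.tsv")
panels <- lapply(manifest$pipeline_id, function(id)
  read_panel(file.path("results/data/panels", paste0(id, ".tsv")), id))
names(panels) <- manifest$pipeline_id

ctrl <- design$sample_id[design$treatment == "T0"]
hkg <- filter_expressed(panels, ctrl, min_units = 4)
med_cov <- median_gene_cov(panels, ctrl)
controls <- sort(hkg$gene_ids)[1:2]   # stand-ins for GAPDH/ACTB
cand <- select_candidates(hkg, med_cov, controls = controls, seed = seed)

truth <- read_truth("results/data/truth.json")
ct <- generate_ct_table(truth, genes = union(cand$gene_ids,
                                             truth$stable_gene),
                        seed = seed)
write_ct(ct, "results/data/ct_table.tsv")

jsonlite::write_json(list(hkg = hkg$gene_ids, provenance = hkg$provenance),
                     "results/hkg_set.json", auto_unbox = TRUE)
jsonlite::write_json(cand[c("high_cov", "low_cov", "mid_random", "controls",
                            "gene_ids")],
                     "results/candidate_set.json", auto_unbox = TRUE)

cat(sprintf("housekeeping set: %d of %d genes pass the filter in all %d pipelines\n",
            length(hkg$gene_ids), nrow(panels[[1]]$values), length(panels)))
cat(sprintf("candidate set: %d genes (10 high-CoV, 10 low-CoV, 10 mid, %d controls)\n",
            length(cand$gene_ids), length(cand$controls)))
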