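Package: rgeqbench
Title: Rank-Based Benchmarking of RNA-Seq Quantification Pipelines Against qRT-PCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores RNA-seq quantification pipelines for precision (non-parametric
    coefficient of variation of housekeeping genes, rank-aggregated across
    pipelines) and accuracy (Pearson correlation against qRT-PCR cycle-threshold
    values, rank-aggregated), and combines both into an overall pipeline ranking.
    Implements qRT-PCR delta-Ct normalization under endogenous-control,
    global-median and most-stable-gene schemes, with reference-gene stability
    estimated by geNorm, NormFinder, BestKeeper and the comparative delta-Ct
    method plus a geometric-mean consensus. Evaluates differential-expression
    result tables against qRT-PCR truth with seven diagnostic parameters (TPR,
    TNR, PPV, NPV, ACC, AUC, MCC) at multiple FDR cut-offs, counts DEGs, and
    clusters methods by call similarity (Euclidean distance, UPGMA). Group
    comparisons of pipeline ranks use Kruskal-Wallis with Dunn's post-hoc test
    and Benjamini-Hochberg adjustment. A seeded synthetic-data generator with
    planted ground truth (noise ordering, differential-expression effects, a
    most-stable gene) makes the whole workflow testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
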