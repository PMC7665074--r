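#' Write / read an expression panel as TSV
#'
#' First column `gene_id`, remaining columns sample ids. UTF-8, '.' decimal
#' separator; CRLF and LF line endings parse identically on read.
#'
#' @param panel an `expression_panel`.
#' @param path file path.
#' @return `read_panel()` returns an `expression_panel` (step labels are
#'   restored from a manifest by the caller if needed).
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(gene_id = rownames(panel$values), panel$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @param pipeline_id id to attach to the panel read back.
#' @export
read_panel <- function(path, pipeline_id = basename(path)) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (names(raw)[1] != "gene_id") stop(path, ": first column must be gene_id")
  dup <- raw$gene_id[duplicated(raw$gene_id)]
  if (length(dup))
    stop(path, ": duplicate gene id(s): ", paste(unique(dup), collapse = ", "),
         " (line ", which(duplicated(raw$gene_id))[1] + 1, ")")
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2, as.numeric))
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(raw$gene_id, colnames(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(path, ": non-numeric cell at line ", bad[1] + 1, ", column ",
         colnames(num)[bad[2]])
  }
  structure(list(values = num, pipeline_id = pipeline_id,
                 trimmer = NA, aligner = NA, counter = NA, normalization = NA),
            class = "expression_panel")
}

#' Write / read a pipeline manifest as TSV
#'
#' @param manifest pipeline-spec data.frame.
#' @param path file path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pipeline_id", "trimmer", "aligner", "counter", "normalization")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop(path, ": missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(m$pipeline_id)) stop(path, ": duplicate pipeline_id")
  m
}

#' Write / read a long-format Ct table as TSV
#'
#' Columns `gene`, `sample`, `duplicate`, `ct`. Read enforces a unique
#' (gene, sample, duplicate) key, finite positive Ct, and the '.' decimal
#' separator (a cell like "30,5" is rejected as non-numeric).
#'
#' @param ct Ct data.frame.
#' @param path file path.
#' @export
write_ct <- function(ct, path) {
  utils::write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct
#' @export
read_ct <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("gene", "sample", "duplicate", "ct")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop(path, ": missing column(s): ",
                         paste(miss, collapse = ", "))
  ctv <- suppressWarnings(as.numeric(raw$ct))
  if (anyNA(ctv))
    stop(path, ": non-numeric ct value at line ", which(is.na(ctv))[1] + 1)
  if (any(ctv <= 0))
    stop(path, ": non-positive ct value at line ", which(ctv <= 0)[1] + 1)
  dup <- duplicated(raw[c("gene", "sample", "duplicate")])
  if (any(dup)) stop(path, ": duplicate (gene, sample, duplicate) key at line ",
                     which(dup)[1] + 1)
  data.frame(gene = raw$gene, sample = raw$sample,
             duplicate = as.integer(raw$duplicate), ct = ctv,
             stringsAsFactors = FALSE)
}

#' Write a truth set as JSON
#'
#' @param truth a `truth_set`.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(
    gene_ids = truth$gene_ids,
    mu = as.data.frame(truth$mu),
    de_labels = as.data.frame(truth$de_labels),
    log2fc = as.data.frame(truth$log2fc),
    contrasts = truth$contrasts,
    stable_gene = truth$stable_gene,
    design = truth$design,
    seed = truth$seed), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  mu <- as.matrix(tr$mu); rownames(mu) <- tr$gene_ids
  de <- as.matrix(tr$de_labels); rownames(de) <- tr$gene_ids
  fc <- as.matrix(tr$log2fc); rownames(fc) <- tr$gene_ids
  structure(list(gene_ids = tr$gene_ids, mu = mu, de_labels = de,
                 log2fc = fc, contrasts = tr$contrasts,
                 stable_gene = tr$stable_gene, design = tr$design,
                 seed = as.integer(tr$seed)),
            class = "truth_set")
}

#' Default run configuration for the end-to-end synthetic benchmark
#'
#' Thresholds mirror the benchmark defaults: expression filter at 4 units on
#' the control samples, Ct ceiling 35, FDR cut-offs 0.05/0.01/0.001, and a
#' 10 + 10 + 10 + 2 candidate rule.
#'
#' @param outdir output directory.
#' @param n_genes genes to simulate.
#' @param manifest pipeline manifest (data.frame); default a small factorial
#'   manifest.
#' @param design sample sheet.
#' @param de_fraction,effect_size planted DE parameters.
#' @param min_units,ct_ceiling,fdr_cutoffs thresholds.
#' @param n_high,n_low,n_mid candidate group sizes.
#' @param exclude_normalizations labels removed in the second group-stats
#'   pass.
#' @param seed global seed, split into per-stage substreams.
#' @return named list (a run config).
#' @export
run_config <- function(outdir = tempfile("rgeqbench_run_"),
                       n_genes = 400,
                       manifest = pipeline_manifest(
                         aligners = c("STAR", "TopHat2"),
                         counters = c("HTSeq_Union", "Cufflinks"),
                         normalizations = c("TMM", "RLE", "TPM", "raw")),
                       design = sample_sheet(),
                       de_fraction = 0.15, effect_size = 2,
                       min_units = 4, ct_ceiling = 35,
                       fdr_cutoffs = c(0.05, 0.01, 0.001),
                       n_high = 10, n_low = 10, n_mid = 10,
                       controls = 2,
                       exclude_normalizations = "raw",
                       seed = 1L) {
  if (any(diff(fdr_cutoffs) >= 0)) stop("fdr cut-offs must strictly decrease")
  list(outdir = outdir, n_genes = n_genes, manifest = manifest,
       design = design, de_fraction = de_fraction, effect_size = effect_size,
       min_units = min_units, ct_ceiling = ct_ceiling,
       fdr_cutoffs = fdr_cutoffs, n_high = n_high, n_low = n_low,
       n_mid = n_mid, controls = controls,
       exclude_normalizations = exclude_normalizations,
       seed = as.integer(seed))
}

#' Run the full synthetic benchmark end to end
#'
#' Simulates panels and a paired Ct table with planted ground truth, selects
#' the housekeeping and candidate gene sets, computes reference-gene
#' stability and the three delta-Ct schemes, scores every pipeline for
#' precision and accuracy, tests algorithm groups, evaluates synthetic DE
#' stand-ins against the qRT-PCR truth, writes all tables under
#' `config$outdir`, and returns a summary list (also written as JSON).
#'
#' @param config a [run_config()] list.
#' @param quiet suppress progress messages.
#' @return summary list (invisibly the same as `summary.json`).
#' @export
run_all <- function(config = run_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message("[rgeqbench] ", ...)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)

  say("simulate: ", config$n_genes, " genes x ", nrow(config$manifest),
      " pipelines")
  truth <- generate_truth(config$n_genes, config$design,
                          de_fraction = config$de_fraction,
                          effect_size = config$effect_size,
                          seed = config$seed)
  panels <- generate_panels(truth, config$manifest, seed = config$seed)
  write_manifest(config$manifest, out("manifest.tsv"))
  write_truth(truth, out("truth.json"))

  design <- config$design
  control_t <- design$treatment[1]
  lines <- unique(design$cell_line)
  ctrl_samples <- lapply(lines, function(cl)
    design$sample_id[design$cell_line == cl & design$treatment == control_t])
  names(ctrl_samples) <- lines

  say("housekeeping filter (>= ", config$min_units, " units)")
  hkg <- filter_expressed(panels, unlist(ctrl_samples), config$min_units)
  if (length(hkg$gene_ids) < config$n_high + config$n_low + config$n_mid + 2)
    stop("stage hkg_selection: too few housekeeping genes (",
         length(hkg$gene_ids), ")")
  med_cov <- median_gene_cov(panels, unlist(ctrl_samples))
  controls <- utils::head(sort(hkg$gene_ids), config$controls)
  cand <- select_candidates(hkg, med_cov, controls = controls,
                            n_high = config$n_high, n_low = config$n_low,
                            n_mid = config$n_mid, seed = config$seed)

  say("qRT-PCR simulation and reference-gene stability")
  assayed <- union(cand$gene_ids, truth$stable_gene)
  ct <- generate_ct_table(truth, genes = assayed, seed = config$seed)
  write_ct(ct, out("ct_table.tsv"))
  groups <- stats::setNames(design$cell_line, design$sample_id)
  stab <- list(stability_genorm(ct), stability_normfinder(ct, groups),
               stability_bestkeeper(ct), stability_comparative_dct(ct))
  cons <- consensus_rank(stab)
  stab_tab <- do.call(rbind, lapply(stab, function(s)
    data.frame(gene = s$gene, method = attr(s, "method"), value = s$value,
               rank = s$rank, stringsAsFactors = FALSE)))
  utils::write.table(stab_tab, out("stability.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  dct_endo <- delta_ct_endogenous(ct, controls)
  dct_gm <- delta_ct_global_median(ct, config$ct_ceiling)
  dct_ms <- delta_ct_most_stable(ct, cons)
  for (d in list(dct_endo, dct_gm, dct_ms))
    utils::write.table(d, out(paste0("delta_ct_", attr(d, "scheme"), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  say("pipeline precision / accuracy ranking")
  prec <- lapply(ctrl_samples, function(s) precision_index(panels, hkg, s))
  acc <- lapply(ctrl_samples, function(s)
    accuracy_index(panels, ct, cand, s))
  scores <- overall_ranking(prec, acc)
  utils::write.table(score_table_export(scores, config$manifest),
                     out("pipeline_scores.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  say("algorithm-group comparisons")
  steps <- c("trimmer", "aligner", "counter", "normalization")
  steps <- steps[vapply(steps, function(st)
    length(unique(config$manifest[[st]])) > 1, logical(1))]
  group_tests <- lapply(steps, function(st)
    compare_step(scores, config$manifest, st,
                 exclude_normalizations =
                   if (st == "normalization") NULL else
                     config$exclude_normalizations))
  names(group_tests) <- steps
  pw <- do.call(rbind, lapply(steps, function(st) {
    g <- group_tests[[st]]$all
    data.frame(step = st, g$pairwise, stringsAsFactors = FALSE)
  }))
  utils::write.table(pw, out("group_tests.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  say("differential-expression evaluation")
  registry <- de_method_registry()
  de_res <- synthetic_de_results(truth, registry$method, seed = config$seed)
  truth_labels <- lapply(seq_len(nrow(truth$contrasts)), function(i) {
    ca <- truth$contrasts$cond_a[i]; cb <- truth$contrasts$cond_b[i]
    ga <- design$sample_id[condition_of(design) == ca]
    gb <- design$sample_id[condition_of(design) == cb]
    lapply(config$fdr_cutoffs, function(co)
      qpcr_de_truth(dct_gm, ga, gb, fdr = co))
  })
  names(truth_labels) <- truth$contrasts$name

  metrics <- list()
  for (m in registry$method) for (i in seq_len(nrow(truth$contrasts))) {
    cn <- truth$contrasts$name[i]
    # diagnostics are computed over the qRT-PCR-assayed genes only
    res <- de_res[[m]][[cn]]
    res <- res[res$gene %in% assayed, , drop = FALSE]
    for (k in seq_along(config$fdr_cutoffs)) {
      co <- config$fdr_cutoffs[k]
      tl <- truth_labels[[cn]][[k]]
      cnt <- confusion(res, tl, cutoff = co)
      dg <- diagnostics(cnt, stats::setNames(res$adj_p, res$gene), tl)
      metrics[[length(metrics) + 1]] <- data.frame(
        method = m, contrast = cn, cutoff = co,
        as.data.frame(dg), stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, metrics)
  utils::write.table(metrics, out("de_diagnostics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  counts <- deg_counts(de_res, config$fdr_cutoffs)
  utils::write.table(counts, out("deg_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  perf <- performance_rank(metrics)
  sim <- method_similarity(lapply(de_res, `[[`, truth$contrasts$name[1]),
                           cutoff = config$fdr_cutoffs[1])

  summary <- list(
    version = 1L,
    seed = config$seed,
    n_genes = config$n_genes,
    n_pipelines = nrow(config$manifest),
    n_samples = nrow(design),
    n_hkg = length(hkg$gene_ids),
    n_candidates = length(cand$gene_ids),
    most_stable = cons$most_stable,
    planted_stable = truth$stable_gene,
    stable_recovered = identical(cons$most_stable, truth$stable_gene),
    top_pipeline = top_n(scores, 1),
    top10 = top_n(scores, min(10, nrow(scores))),
    kw_p_by_step = lapply(group_tests, function(g) g$all$p),
    n_de_methods = nrow(registry),
    best_de_method = perf$overall$method[1],
    deg_total = sum(counts$n_deg))
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("done: ", config$outdir)
  invisible(summary)
}

# Score table joined with step labels, in the published column layout.
score_table_export <- function(scores, manifest) {
  idx <- match(scores$pipeline_id, manifest$pipeline_id)
  data.frame(ranking = scores$rank,
             trimmer = manifest$trimmer[idx],
             aligner = manifest$aligner[idx],
             counter = manifest$counter[idx],
             normalization = manifest$normalization[idx],
             median_precision = scores$median_precision,
             median_accuracy = scores$median_accuracy,
             median_overall_precision_and_accuracy = scores$overall,
             pipeline_id = scores$pipeline_id,
             stringsAsFactors = FALSE)
}
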