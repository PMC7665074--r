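#' Filter genes constitutively expressed across all pipelines
#'
#' Keeps the genes whose expression is at least `min_units` in every listed
#' sample of every panel — the housekeeping (HKg) reference-set rule. Genes
#' falling below the threshold in any single sample of any single pipeline
#' are removed; the boundary value itself is kept (>=).
#'
#' @param panels list of `expression_panel` objects.
#' @param samples sample ids to examine (typically the untreated controls).
#' @param min_units expression threshold, default 4.
#' @return an object of class `hkg_set`: list with `gene_ids` (input gene
#'   order preserved) and `provenance` (threshold, samples, panels examined).
#' @export
filter_expressed <- function(panels, samples, min_units = 4) {
  if (length(panels) == 0) stop("empty panel collection")
  genes <- rownames(panels[[1]]$values)
  for (p in panels) {
    missing <- setdiff(samples, colnames(p$values))
    if (length(missing))
      stop("sample(s) missing from panel ", p$pipeline_id, ": ",
           paste(missing, collapse = ", "))
    genes <- intersect(genes, rownames(p$values))
  }
  keep <- rep(TRUE, length(genes))
  for (p in panels) {
    sub <- p$values[genes, samples, drop = FALSE]
    keep <- keep & apply(sub >= min_units, 1, all)
  }
  structure(list(gene_ids = genes[keep],
                 provenance = list(min_units = min_units, samples = samples,
                                   panels = vapply(panels, `[[`, "",
                                                   "pipeline_id"))),
            class = "hkg_set")
}

#' Select qRT-PCR candidate genes by the high/low/mid CoV rule
#'
#' From the housekeeping set, picks the `n_high` genes with the largest
#' median CoV, the `n_low` with the smallest, `n_mid` genes sampled uniformly
#' (seeded) from the remaining middle stratum, and appends the designated
#' control genes regardless of their CoV. Defaults (10 + 10 + 10 + 2
#' controls) give a 32-gene candidate list. Ties in median CoV at a group
#' boundary are broken by lexicographic gene id. Control genes are excluded
#' from the high/low/mid draws even when they would qualify.
#'
#' @param hkg an `hkg_set` (or character vector of gene ids).
#' @param median_cov named numeric: per-gene median CoV across pipelines.
#' @param controls control gene ids (appended verbatim).
#' @param n_high,n_low,n_mid group sizes.
#' @param seed integer RNG seed for the mid-stratum draw.
#' @return an object of class `candidate_set`: list with `high_cov`,
#'   `low_cov`, `mid_random`, `controls`, `seed`, and `gene_ids` (the union,
#'   in high/low/mid/controls order).
#' @export
select_candidates <- function(hkg, median_cov, controls = character(),
                              n_high = 10, n_low = 10, n_mid = 10, seed = 1L) {
  genes <- if (inherits(hkg, "hkg_set")) hkg$gene_ids else as.character(hkg)
  if (!all(controls %in% genes))
    stop("control gene(s) absent from the expression universe: ",
         paste(setdiff(controls, genes), collapse = ", "))
  eligible <- setdiff(genes, controls)
  if (length(eligible) < n_high + n_low + n_mid)
    stop("insufficient genes: need ", n_high + n_low + n_mid,
         " non-control genes, have ", length(eligible))
  if (!all(eligible %in% names(median_cov)))
    stop("`median_cov` missing for: ",
         paste(setdiff(eligible, names(median_cov)), collapse = ", "))
  cov <- median_cov[eligible]

  high <- eligible[order(-cov, eligible)][seq_len(n_high)]
  rest <- setdiff(eligible, high)
  low <- rest[order(cov[rest], rest)][seq_len(n_low)]
  mid_pool <- sort(setdiff(rest, low))
  mid <- if (n_mid == length(mid_pool)) mid_pool else
    with_seed(sub_seed(seed, "candidates"),
              sort(sample(mid_pool, n_mid)))

  structure(list(high_cov = high, low_cov = low, mid_random = mid,
                 controls = controls, seed = as.integer(seed),
                 gene_ids = c(high, low, mid, controls)),
            class = "candidate_set")
}

#' Median per-gene CoV across pipelines
#'
#' Computes, for each gene, the non-parametric CoV ([gene_cov()]) within each
#' panel over the listed samples, and returns the per-gene median across
#' panels (undefined CoVs ignored; a gene undefined everywhere gets NA).
#'
#' @param panels list of `expression_panel` objects.
#' @param samples sample ids over which dispersion is measured.
#' @return named numeric vector over the genes common to all panels.
#' @export
median_gene_cov <- function(panels, samples) {
  if (length(panels) == 0) stop("empty panel collection")
  genes <- Reduce(intersect, lapply(panels, function(p) rownames(p$values)))
  covs <- vapply(panels, function(p) {
    apply(p$values[genes, samples, drop = FALSE], 1, gene_cov)
  }, numeric(length(genes)))
  apply(matrix(covs, nrow = length(genes)), 1, stats::median, na.rm = TRUE) |>
    stats::setNames(genes)
}
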