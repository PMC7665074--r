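#' Non-parametric coefficient of variation (MAD / median)
#'
#' `CoV = MAD / median` with `MAD = median(|x_i - median(x)|)` (no
#' consistency factor). Unit-free: invariant under positive rescaling of
#' `x`. Undefined (NA) when the median is zero.
#'
#' @param x numeric vector of expression values, length >= 2, finite.
#' @return non-negative numeric, or NA when the median is 0.
#' @export
gene_cov <- function(x) {
  if (length(x) < 2) stop("need at least 2 values")
  if (any(!is.finite(x))) stop("values must be finite")
  m <- stats::median(x)
  if (m == 0) return(NA_real_)
  stats::median(abs(x - m)) / m
}

#' Pipeline precision index from housekeeping-gene CoV ranks
#'
#' For each housekeeping gene, the CoV over the given replicate samples is
#' computed within every pipeline; pipelines are then ranked per gene
#' (ascending CoV, rank 1 = lowest dispersion, average ranks on ties), and a
#' pipeline's precision index is the median of its per-gene ranks. Lower is
#' more precise. Genes whose CoV is undefined in any pipeline are dropped
#' from the ranking universe (reported in `dropped`).
#'
#' @param panels list of `expression_panel` objects.
#' @param genes housekeeping gene ids (an `hkg_set` or character vector).
#' @param samples replicate sample ids of one cell line's controls (>= 2).
#' @return list of class `precision_result`: `index` (named per pipeline),
#'   `cov` and `ranks` (genes x pipelines matrices, kept for audit),
#'   `dropped` (gene ids excluded).
#' @export
precision_index <- function(panels, genes, samples) {
  genes <- if (inherits(genes, "hkg_set")) genes$gene_ids else
    as.character(genes)
  if (length(genes) == 0) stop("empty housekeeping gene set")
  if (length(samples) < 2) stop("need >= 2 replicate samples")
  cov <- metric_matrix(panels, genes, samples, function(vals)
    apply(vals, 1, gene_cov))
  rank_index(cov, na_last = FALSE)
}

#' Pearson correlation between expression and Ct
#'
#' Association between a pipeline's expression values and the qRT-PCR Ct
#' values of the same gene over the same samples. Because Ct is inversely
#' related to abundance, accurate quantification gives strongly negative r.
#' Undefined (NA) when either vector is constant.
#'
#' @param expression,ct aligned numeric vectors, length >= 3.
#' @return r in \[-1, 1\], or NA when undefined.
#' @export
accuracy_correlation <- function(expression, ct) {
  if (length(expression) != length(ct)) stop("length mismatch")
  if (length(expression) < 3) stop("need at least 3 paired samples")
  if (stats::sd(expression) == 0 || stats::sd(ct) == 0) return(NA_real_)
  stats::cor(expression, ct, method = "pearson")
}

#' Pipeline accuracy index from expression-vs-Ct correlation ranks
#'
#' For each candidate gene, Pearson r between the pipeline's expression and
#' the duplicate-averaged Ct is computed over the given samples; pipelines
#' are ranked per gene ascending in r (rank 1 = most negative r, the
#' strongest inverse Ct association; ties averaged; undefined r ranked
#' last), and a pipeline's accuracy index is the median of its per-gene
#' ranks. Lower is more accurate.
#'
#' @param panels list of `expression_panel` objects.
#' @param ct a Ct table (long data.frame); duplicates are averaged.
#' @param genes candidate gene ids (a `candidate_set` or character vector).
#' @param samples sample ids of one cell line (>= 3).
#' @return list of class `accuracy_result`: `index`, `r` and `ranks`
#'   matrices, `dropped` (empty; undefined r is ranked last, not dropped).
#' @export
accuracy_index <- function(panels, ct, genes, samples) {
  genes <- if (inherits(genes, "candidate_set")) genes$gene_ids else
    as.character(genes)
  if (length(genes) == 0) stop("empty candidate gene set")
  if (length(samples) < 3) stop("need >= 3 samples")
  ctm <- ct_matrix(ct)
  if (!all(genes %in% rownames(ctm)))
    stop("gene(s) missing from Ct table: ",
         paste(setdiff(genes, rownames(ctm)), collapse = ", "))
  if (!all(samples %in% colnames(ctm)))
    stop("sample(s) missing from Ct table: ",
         paste(setdiff(samples, colnames(ctm)), collapse = ", "))
  ct_sub <- ctm[genes, samples, drop = FALSE]
  r <- metric_matrix(panels, genes, samples, function(vals)
    vapply(seq_len(nrow(vals)), function(i)
      accuracy_correlation(vals[i, ], ct_sub[i, ]), numeric(1)))
  res <- rank_index(r, na_last = TRUE)
  names(res)[names(res) == "cov"] <- "r"
  class(res) <- "accuracy_result"
  res
}

# Apply a per-panel metric over a gene x sample block; returns genes x
# pipelines matrix.
metric_matrix <- function(panels, genes, samples, fn) {
  if (length(panels) == 0) stop("empty panel collection")
  out <- vapply(panels, function(p) {
    miss <- setdiff(genes, rownames(p$values))
    if (length(miss))
      stop("gene(s) missing from panel ", p$pipeline_id, ": ",
           paste(miss, collapse = ", "))
    miss_s <- setdiff(samples, colnames(p$values))
    if (length(miss_s))
      stop("sample(s) missing from panel ", p$pipeline_id, ": ",
           paste(miss_s, collapse = ", "))
    fn(p$values[genes, samples, drop = FALSE])
  }, numeric(length(genes)))
  out <- matrix(out, nrow = length(genes),
                dimnames = list(genes, vapply(panels, `[[`, "", "pipeline_id")))
  out
}

# Rank a genes x pipelines metric matrix per gene (ascending, average ties)
# and take per-pipeline median ranks. na_last = TRUE ranks NA as worst
# (tied at +Inf); na_last = FALSE drops genes with any NA.
rank_index <- function(metric, na_last) {
  dropped <- character()
  if (!na_last) {
    bad <- apply(metric, 1, function(r) any(is.na(r)))
    dropped <- rownames(metric)[bad]
    metric <- metric[!bad, , drop = FALSE]
    if (nrow(metric) == 0) stop("no gene has a defined metric in all pipelines")
  }
  ranks <- t(apply(metric, 1, function(r) {
    r[is.na(r)] <- Inf
    rank(r, ties.method = "average")
  }))
  ranks <- matrix(ranks, nrow = nrow(metric), dimnames = dimnames(metric))
  idx <- apply(ranks, 2, stats::median)
  structure(list(index = idx, cov = metric, ranks = ranks, dropped = dropped),
            class = "precision_result")
}

#' Combine per-cell-line precision and accuracy into an overall ranking
#'
#' A pipeline's overall index is the sum, over cell lines, of its precision
#' and accuracy indices — equal weight to both criteria. With exactly two
#' cell lines this equals `2 * (median precision + median accuracy)` since
#' the median of two values is their mean. The final rank is ascending in
#' the overall index; ties are broken by median accuracy, then pipeline id.
#'
#' @param precision named list (cell line) of precision results (or bare
#'   named index vectors).
#' @param accuracy named list (cell line) of accuracy results, same cell
#'   lines and pipelines.
#' @return data.frame of class `pipeline_score_table`: `pipeline_id`,
#'   `median_precision`, `median_accuracy`, `overall`, `rank`, sorted by
#'   rank.
#' @export
overall_ranking <- function(precision, accuracy) {
  get_idx <- function(x) if (is.list(x) && !is.null(x$index)) x$index else x
  prec <- lapply(precision, get_idx)
  acc <- lapply(accuracy, get_idx)
  if (!identical(sort(names(prec)), sort(names(acc))))
    stop("cell-line sets differ between precision and accuracy")
  pipes <- names(prec[[1]])
  for (v in c(prec, acc))
    if (!identical(sort(names(v)), sort(pipes)))
      stop("pipeline sets differ across results")
  pm <- vapply(prec, function(v) v[pipes], numeric(length(pipes)))
  am <- vapply(acc, function(v) v[pipes], numeric(length(pipes)))
  pm <- matrix(pm, nrow = length(pipes)); am <- matrix(am, nrow = length(pipes))
  overall <- rowSums(pm) + rowSums(am)
  med_p <- apply(pm, 1, stats::median)
  med_a <- apply(am, 1, stats::median)
  out <- data.frame(pipeline_id = pipes, median_precision = med_p,
                    median_accuracy = med_a, overall = overall,
                    stringsAsFactors = FALSE)
  out <- out[order(out$overall, out$median_accuracy, out$pipeline_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("pipeline_score_table", "data.frame")
  out
}

#' Top-n pipelines of a score table
#'
#' @param table a [overall_ranking()] result.
#' @param n number of pipelines, 1 <= n <= nrow(table).
#' @return character vector of pipeline ids in final-rank order.
#' @export
top_n <- function(table, n) {
  if (n <= 0) stop("`n` must be positive")
  if (n > nrow(table)) stop("`n` exceeds the number of pipelines")
  table$pipeline_id[order(table$rank)][seq_len(n)]
}
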