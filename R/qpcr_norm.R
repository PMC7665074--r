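#' Average technical duplicates of a Ct table
#'
#' @param ct long-format data.frame with columns `gene`, `sample`,
#'   `duplicate`, `ct`.
#' @return data.frame with one row per (gene, sample) and columns `gene`,
#'   `sample`, `ct` (arithmetic mean over duplicates).
#' @export
average_duplicates <- function(ct) {
  stopifnot(all(c("gene", "sample", "ct") %in% names(ct)))
  agg <- stats::aggregate(ct ~ gene + sample, data = ct, FUN = mean)
  agg[order(agg$gene, agg$sample), c("gene", "sample", "ct")] |>
    (\(d) { rownames(d) <- NULL; d })()
}

# Genes x samples Ct matrix from a long table (duplicates averaged first if
# a `duplicate` column is present). Matrices pass through unchanged.
ct_matrix <- function(ct) {
  if (is.matrix(ct)) return(ct)
  avg <- if ("duplicate" %in% names(ct)) average_duplicates(ct) else ct
  genes <- unique(avg$gene); samples <- unique(avg$sample)
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(avg$gene, avg$sample)] <- avg$ct
  if (anyNA(m)) stop("Ct table is not complete over genes x samples")
  m
}

new_delta_ct <- function(m, scheme, params) {
  out <- data.frame(gene = rep(rownames(m), ncol(m)),
                    sample = rep(colnames(m), each = nrow(m)),
                    delta_ct = as.vector(m), stringsAsFactors = FALSE)
  structure(out, scheme = scheme, params = params,
            class = c("delta_ct_table", "data.frame"))
}

#' Delta-Ct with endogenous-control normalization
#'
#' `dCt[g, s] = mean(control-gene Ct in s) - Ct[g, s]`; larger delta-Ct
#' means higher expression. Duplicates are averaged first.
#'
#' @param ct a Ct table (long data.frame or genes x samples matrix).
#' @param control_genes gene ids of the endogenous controls (e.g. GAPDH and
#'   ACTB); must be measured in every sample.
#' @return `delta_ct_table` data.frame (`gene`, `sample`, `delta_ct`) with
#'   attributes `scheme` and `params`.
#' @export
delta_ct_endogenous <- function(ct, control_genes) {
  m <- ct_matrix(ct)
  miss <- setdiff(control_genes, rownames(m))
  if (length(miss))
    stop("control gene(s) missing from Ct table: ",
         paste(miss, collapse = ", "))
  factor <- colMeans(m[control_genes, , drop = FALSE])
  new_delta_ct(sweep(-m, 2, factor, `+`), "endogenous",
               list(control_genes = control_genes))
}

#' Delta-Ct with global-median normalization
#'
#' The per-sample normalization factor is the median Ct over genes with
#' `Ct < ct_ceiling` (strict) in that sample;
#' `dCt[g, s] = factor(s) - Ct[g, s]`.
#'
#' @param ct a Ct table.
#' @param ct_ceiling exclusion ceiling in cycles, default 35.
#' @return `delta_ct_table` data.frame.
#' @export
delta_ct_global_median <- function(ct, ct_ceiling = 35) {
  m <- ct_matrix(ct)
  factor <- vapply(colnames(m), function(s) {
    v <- m[, s][m[, s] < ct_ceiling]
    if (length(v) == 0)
      stop("sample ", s, " has no gene with Ct < ", ct_ceiling)
    stats::median(v)
  }, numeric(1))
  new_delta_ct(sweep(-m, 2, factor, `+`), "global_median",
               list(ct_ceiling = ct_ceiling))
}

#' Delta-Ct normalized to the most stable gene
#'
#' `dCt[g, s] = Ct[stable, s] - Ct[g, s]`, with the stable gene taken from a
#' stability consensus (or given directly).
#'
#' @param ct a Ct table.
#' @param consensus a [consensus_rank()] result, or a single gene id.
#' @return `delta_ct_table` data.frame.
#' @export
delta_ct_most_stable <- function(ct, consensus) {
  stable <- if (inherits(consensus, "consensus_ranking"))
    consensus$most_stable else as.character(consensus)
  m <- ct_matrix(ct)
  if (!stable %in% rownames(m))
    stop("stable gene ", stable, " missing from Ct table")
  new_delta_ct(sweep(-m, 2, m[stable, ], `+`), "most_stable",
               list(stable_gene = stable))
}

new_stability <- function(method, value) {
  data.frame(gene = names(value), value = unname(value),
             rank = rank(unname(value), ties.method = "average"),
             stringsAsFactors = FALSE) |>
    structure(method = method, class = c("stability_result", "data.frame"))
}

# SD over samples of the pairwise Ct difference of every gene pair.
pairwise_sd <- function(m) {
  n <- nrow(m)
  V <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    V[j, k] <- V[k, j] <- stats::sd(m[j, ] - m[k, ])
  }
  V
}

#' geNorm expression-stability measure M
#'
#' Pairwise variation `V_jk` is the standard deviation over samples of the
#' Ct difference between genes j and k; `M_j` is the mean of `V_jk` over all
#' other genes. The gene with the highest M is excluded and M recomputed,
#' iteratively, until two genes remain; a gene's stability value is its M
#' from the round in which it was excluded (the final pair shares the last
#' M). Lower M = more stable. Invariant to adding per-sample constants.
#'
#' @param ct a Ct table (duplicates averaged internally); >= 3 genes, >= 2
#'   samples.
#' @return `stability_result` data.frame (`gene`, `value`, `rank`).
#' @export
stability_genorm <- function(ct) {
  m <- ct_matrix(ct)
  if (nrow(m) < 3) stop("geNorm needs at least 3 genes")
  if (ncol(m) < 2) stop("geNorm needs at least 2 samples")
  value <- stats::setNames(numeric(nrow(m)), rownames(m))
  keep <- rownames(m)
  repeat {
    V <- pairwise_sd(m[keep, , drop = FALSE])
    M <- rowMeans(V) * length(keep) / (length(keep) - 1)  # mean over k != j
    if (length(keep) == 2) { value[keep] <- M; break }
    worst <- keep[order(-M, keep)][1]  # ties: lexicographic gene id
    value[worst] <- M[worst]
    keep <- setdiff(keep, worst)
  }
  new_stability("genorm", value)
}

#' Comparative delta-Ct stability
#'
#' Mean, over all other genes, of the SD over samples of the pairwise Ct
#' difference — geNorm's first-round M without any iterative exclusion.
#'
#' @param ct a Ct table; >= 2 genes, >= 2 samples.
#' @return `stability_result` data.frame.
#' @export
stability_comparative_dct <- function(ct) {
  m <- ct_matrix(ct)
  if (nrow(m) < 2) stop("comparative delta-Ct needs at least 2 genes")
  V <- pairwise_sd(m)
  M <- rowMeans(V) * nrow(m) / (nrow(m) - 1)
  new_stability("comparative_dct", stats::setNames(M, rownames(m)))
}

#' BestKeeper stability (SD of Ct) and index correlation
#'
#' The primary stability value is the sample standard deviation of each
#' gene's Ct (lower = more stable); ranking uses the SD. The per-gene
#' Pearson correlation with the BestKeeper index — the per-sample arithmetic
#' mean Ct across genes — is reported alongside (NA when the index is
#' constant).
#'
#' @param ct a Ct table; >= 2 genes.
#' @return `stability_result` data.frame with an extra `index_cor` column.
#' @export
stability_bestkeeper <- function(ct) {
  m <- ct_matrix(ct)
  if (nrow(m) < 2) stop("BestKeeper needs at least 2 genes")
  sds <- apply(m, 1, stats::sd)
  index <- colMeans(m)
  cors <- if (stats::sd(index) == 0) rep(NA_real_, nrow(m)) else
    apply(m, 1, function(x)
      if (stats::sd(x) == 0) NA_real_ else stats::cor(x, index))
  out <- new_stability("bestkeeper", stats::setNames(sds, rownames(m)))
  out$index_cor <- unname(cors)
  out
}

#' NormFinder-style stability by intra/inter-group variance decomposition
#'
#' Operates on duplicate-averaged Ct values. For gene i and sample group g
#' (default grouping: cell line): `m_ig` is the group mean, `v_ig` the
#' intra-group sample variance, and `d_ig = m_ig - mean_g(m_ig)` the
#' centred inter-group deviation. The stability value is
#' `mean_g |d_ig| + sqrt(mean_g v_ig)` — the absolute inter-group difference
#' estimate plus the averaged intra-group variation; lower = more stable.
#' A gene with zero intra-group variance and equal group means scores 0.
#'
#' @param ct a Ct table; >= 3 genes.
#' @param groups named character: sample id -> group label; >= 2 groups with
#'   >= 2 samples each.
#' @return `stability_result` data.frame.
#' @export
stability_normfinder <- function(ct, groups) {
  m <- ct_matrix(ct)
  if (nrow(m) < 3) stop("NormFinder needs at least 3 genes")
  g <- groups[colnames(m)]
  if (anyNA(g)) stop("group label missing for some samples")
  tab <- table(g)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("every group needs at least 2 samples")
  lv <- names(tab)
  value <- apply(m, 1, function(x) {
    mg <- vapply(lv, function(k) mean(x[g == k]), numeric(1))
    vg <- vapply(lv, function(k) stats::var(x[g == k]), numeric(1))
    d <- mg - mean(mg)
    mean(abs(d)) + sqrt(mean(vg))
  })
  new_stability("normfinder", stats::setNames(value, rownames(m)))
}

#' Consensus reference-gene ranking across stability estimators
#'
#' Aggregates the per-gene ranks of the four stability estimators by their
#' geometric mean; the final ordering is ascending in the consensus value
#' with ties broken by lexicographic gene id, and the first gene is reported
#' as the most stable.
#'
#' @param results list of `stability_result` objects over one gene set.
#' @return object of class `consensus_ranking`: list with `table` (`gene`,
#'   `geo_mean_rank`, method rank columns, `consensus_rank`), `ordering`,
#'   `most_stable`.
#' @export
consensus_rank <- function(results) {
  stopifnot(length(results) >= 2)
  genes <- sort(results[[1]]$gene)
  for (r in results)
    if (!identical(sort(r$gene), genes))
      stop("stability results cover different gene sets")
  ranks <- vapply(results, function(r) r$rank[match(genes, r$gene)],
                  numeric(length(genes)))
  ranks <- matrix(ranks, nrow = length(genes))
  colnames(ranks) <- vapply(results, function(r)
    attr(r, "method") %||% "method", character(1))
  geo <- exp(rowMeans(log(ranks)))
  ord <- order(geo, genes)
  tab <- data.frame(gene = genes, ranks, geo_mean_rank = geo,
                    stringsAsFactors = FALSE, check.names = FALSE)
  tab <- tab[ord, ]
  tab$consensus_rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab, ordering = tab$gene,
                 most_stable = tab$gene[1]),
            class = "consensus_ranking")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
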