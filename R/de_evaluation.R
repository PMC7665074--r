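#' Registry of evaluated differential-expression methods
#'
#' Eleven DE algorithms; edgeR exact, edgeR GLM and NOISeq each carry three
#' internal normalization variants evaluated separately, so the registry
#' enumerates 8 + 3 x 3 = 17 methods.
#'
#' @return data.frame with `method` (unique label), `algorithm`,
#'   `normalization_variant`.
#' @export
de_method_registry <- function() {
  single <- c("baySeq", "Cuffdiff", "DESeq2", "EBSeq", "Ballgown",
              "limma_trend", "limma_voom", "SAMseq")
  multi <- c("edgeR_exact", "edgeR_GLM", "NOISeq")
  variants <- c("TMM", "RLE", "UQ")
  out <- rbind(
    data.frame(method = single, algorithm = single,
               normalization_variant = "default", stringsAsFactors = FALSE),
    do.call(rbind, lapply(multi, function(a)
      data.frame(method = paste(a, variants, sep = "_"), algorithm = a,
                 normalization_variant = variants, stringsAsFactors = FALSE)))
  )
  rownames(out) <- NULL
  out
}

#' qRT-PCR differential-expression truth labels
#'
#' Per gene, a Welch two-sample t-test on normalized delta-Ct values between
#' the two groups of a contrast; p-values are BH-adjusted across genes
#' within the contrast and a gene is labelled DE when its adjusted p falls
#' below the cut-off. When both groups are constant the p-value is 1 for
#' equal means and 0 otherwise.
#'
#' @param delta_ct a `delta_ct_table` (typically from the global-median
#'   scheme).
#' @param group_a,group_b sample ids of the two groups (>= 2 each).
#' @param fdr cut-off on the adjusted p-value, default 0.05.
#' @return list of class `truth_labels`: `gene`, `adj_p`, `raw_p`, `label`
#'   (logical), `fdr`.
#' @export
qpcr_de_truth <- function(delta_ct, group_a, group_b, fdr = 0.05) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 samples")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  wide <- dct_matrix(delta_ct)
  miss <- setdiff(c(group_a, group_b), colnames(wide))
  if (length(miss))
    stop("sample(s) missing from delta-Ct table: ",
         paste(miss, collapse = ", "))
  raw <- apply(wide, 1, function(x) welch_p(x[group_a], x[group_b]))
  adj <- bh_adjust(raw)
  structure(list(gene = rownames(wide), raw_p = unname(raw),
                 adj_p = unname(adj), label = unname(adj < fdr), fdr = fdr),
            class = "truth_labels")
}

dct_matrix <- function(delta_ct) {
  if (is.matrix(delta_ct)) return(delta_ct)
  genes <- unique(delta_ct$gene); samples <- unique(delta_ct$sample)
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(delta_ct$gene, delta_ct$sample)] <- delta_ct$delta_ct
  m
}

#' Confusion counts of a DE result table against truth labels
#'
#' Predicted positive = method adjusted p below the cut-off; counts are
#' cross-tabulated against the truth labels over the identical gene set.
#'
#' @param result data.frame with `gene` and `adj_p`.
#' @param truth a [qpcr_de_truth()] result.
#' @param cutoff adjusted-p cut-off for the method's calls.
#' @return named list `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(result, truth, cutoff = truth$fdr) {
  if (!setequal(result$gene, truth$gene)) stop("gene sets differ")
  pred <- result$adj_p[match(truth$gene, result$gene)] < cutoff
  lab <- truth$label
  list(TP = sum(pred & lab), FP = sum(pred & !lab),
       TN = sum(!pred & !lab), FN = sum(!pred & lab))
}

#' Area under the ROC curve by midranks
#'
#' Mann-Whitney formulation: the probability that a positive gene's score
#' exceeds a negative's, counting ties as 1/2. Invariant to strictly
#' monotone transforms of the score. NA when either class is empty.
#'
#' @param score numeric DE-evidence score (higher = stronger evidence).
#' @param label logical truth labels.
#' @return AUC in \[0, 1\] or NA.
#' @export
auc_midrank <- function(score, label) {
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Seven diagnostic parameters of a DE method at one cut-off
#'
#' TPR (sensitivity), TNR (specificity), PPV, NPV, ACC from the confusion
#' counts; MCC = (TP.TN - FP.FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)) with
#' the convention MCC = 0 when any factor of the denominator is 0; AUC by
#' midranks of the score `1 - adj_p` (smaller adjusted p = stronger DE
#' evidence) against the truth labels.
#'
#' @param counts list with `TP`, `FP`, `TN`, `FN` (see [confusion()]).
#' @param scores per-gene method adjusted p-values aligned with
#'   `truth$gene`; NULL skips the AUC.
#' @param truth a [qpcr_de_truth()] result (needed for the AUC).
#' @return named list with the counts and TPR, TNR, PPV, NPV, ACC, MCC, AUC.
#' @export
diagnostics <- function(counts, scores = NULL, truth = NULL) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  n <- TP + FP + TN + FN
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  den <- prod(c(TP + FP, TP + FN, TN + FP, TN + FN))
  mcc <- if (den == 0) 0 else
    (TP * TN - FP * FN) / sqrt(TP + FP) / sqrt(TP + FN) /
      sqrt(TN + FP) / sqrt(TN + FN)
  auc <- NA_real_
  if (!is.null(scores) && !is.null(truth)) {
    if (!is.null(names(scores))) scores <- scores[match(truth$gene,
                                                        names(scores))]
    auc <- auc_midrank(1 - scores, truth$label)
  }
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       TPR = ratio(TP, TP + FN), TNR = ratio(TN, TN + FP),
       PPV = ratio(TP, TP + FP), NPV = ratio(TN, TN + FN),
       ACC = ratio(TP + TN, n), MCC = mcc, AUC = auc)
}

#' Count differentially expressed genes per method, contrast and cut-off
#'
#' @param results named list (method) of named lists (contrast) of
#'   data.frames with `gene` and `adj_p`.
#' @param cutoffs FDR cut-offs, default `c(0.05, 0.01, 0.001)`.
#' @return data.frame `method`, `contrast`, `cutoff`, `n_deg`.
#' @export
deg_counts <- function(results, cutoffs = c(0.05, 0.01, 0.001)) {
  rows <- list()
  for (m in names(results)) for (ct in names(results[[m]])) {
    p <- results[[m]][[ct]]$adj_p
    for (co in cutoffs) {
      rows[[length(rows) + 1]] <- data.frame(
        method = m, contrast = ct, cutoff = co, n_deg = sum(p < co),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Cluster DE methods by the similarity of their calls
#'
#' Each method is represented by its per-gene vector at the cut-off —
#' binary calls by default, or the adjusted p-values themselves — and
#' methods are clustered by Euclidean distance with unweighted group-average
#' (UPGMA) linkage.
#'
#' @param results named list (method) of data.frames with `gene`, `adj_p`
#'   for one contrast.
#' @param cutoff call cut-off on the adjusted p-value.
#' @param feature `"calls"` (binary, default) or `"adj_p"`.
#' @return list with `dist` (a `dist` object) and `tree` (an `hclust`).
#' @export
method_similarity <- function(results, cutoff = 0.05,
                              feature = c("calls", "adj_p")) {
  feature <- match.arg(feature)
  if (length(results) < 2) stop("need at least 2 methods")
  genes <- sort(results[[1]]$gene)
  feat <- t(vapply(results, function(r) {
    if (!setequal(r$gene, genes)) stop("gene sets differ across methods")
    p <- r$adj_p[match(genes, r$gene)]
    if (feature == "calls") as.numeric(p < cutoff) else p
  }, numeric(length(genes))))
  rownames(feat) <- names(results)
  d <- stats::dist(feat, method = "euclidean")
  list(dist = d, tree = stats::hclust(d, method = "average"))
}

#' Rank DE methods by scenario, by cut-off, and overall
#'
#' `metrics` is a long grid of the seven diagnostic parameters per method,
#' contrast (DEG scenario) and FDR cut-off. For every (contrast, cutoff,
#' parameter) cell the methods are ranked descending (rank 1 = best, ties
#' averaged; all seven parameters are better-is-higher). A method's
#' per-scenario score is its mean rank over parameters and cut-offs within
#' the contrast; its per-cutoff score the mean over parameters and
#' contrasts within the cut-off; its overall score the mean of its scenario
#' and cut-off scores. Undefined parameter values are excluded from the
#' means with a warning.
#'
#' @param metrics data.frame with columns `method`, `contrast`, `cutoff` and
#'   the parameters `TPR`, `TNR`, `PPV`, `NPV`, `ACC`, `AUC`, `MCC`.
#' @return list with `by_scenario`, `by_cutoff`, `overall` data.frames
#'   (`method`, `score`, `rank` — rank 1 = best).
#' @export
performance_rank <- function(metrics) {
  pars <- c("TPR", "TNR", "PPV", "NPV", "ACC", "AUC", "MCC")
  stopifnot(all(c("method", "contrast", "cutoff", pars) %in% names(metrics)))
  if (anyNA(metrics[pars]))
    warning("undefined diagnostic values excluded from rank aggregation")
  cells <- expand.grid(contrast = unique(metrics$contrast),
                       cutoff = unique(metrics$cutoff),
                       par = pars, stringsAsFactors = FALSE)
  long <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- metrics[metrics$contrast == cells$contrast[i] &
                     metrics$cutoff == cells$cutoff[i], ]
    v <- sub[[cells$par[i]]]
    ok <- !is.na(v)
    if (!any(ok)) return(NULL)
    data.frame(method = sub$method[ok], contrast = cells$contrast[i],
               cutoff = cells$cutoff[i], par = cells$par[i],
               rk = rank(-v[ok], ties.method = "average"),
               stringsAsFactors = FALSE)
  }))
  rank_within <- function(d, within) {
    sc <- stats::aggregate(stats::as.formula(paste("rk ~ method +", within)),
                           data = d, FUN = mean)
    names(sc)[names(sc) == "rk"] <- "score"
    sc$rank <- stats::ave(sc$score, sc[[within]],
                          FUN = function(x) rank(x, ties.method = "average"))
    sc[order(sc[[within]], sc$rank, sc$method), ] |>
      (\(x) { rownames(x) <- NULL; x })()
  }
  by_scen <- rank_within(long, "contrast")
  by_cut <- rank_within(long, "cutoff")
  scen_scores <- stats::aggregate(score ~ method, data = by_scen, FUN = mean)
  cut_scores <- stats::aggregate(score ~ method, data = by_cut, FUN = mean)
  overall <- merge(scen_scores, cut_scores, by = "method",
                   suffixes = c("_scenario", "_cutoff"))
  overall$score <- (overall$score_scenario + overall$score_cutoff) / 2
  overall$rank <- rank(overall$score, ties.method = "average")
  overall <- overall[order(overall$rank, overall$method),
                     c("method", "score", "rank")]
  rownames(overall) <- NULL
  list(by_scenario = by_scen, by_cutoff = by_cut, overall = overall)
}
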