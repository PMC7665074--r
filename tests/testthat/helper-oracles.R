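# Independent brute-force re-derivations used as oracles. These are written
# from the definitions, not from the package internals, and favour clarity
# over speed.

# Mean over all other genes of sd(Ct_j - Ct_k): comparative delta-Ct /
# geNorm round-1 M.
oracle_mean_pairwise_sd <- function(m) {
  sapply(rownames(m), function(j) {
    others <- setdiff(rownames(m), j)
    mean(sapply(others, function(k) sd(m[j, ] - m[k, ])))
  })
}

# Full iterative geNorm by explicit recomputation.
oracle_genorm <- function(m) {
  value <- setNames(numeric(nrow(m)), rownames(m))
  keep <- rownames(m)
  while (TRUE) {
    M <- oracle_mean_pairwise_sd(m[keep, , drop = FALSE])
    if (length(keep) == 2) { value[keep] <- M; break }
    worst <- sort(names(M)[M == max(M)])[1]
    value[worst] <- M[worst]
    keep <- setdiff(keep, worst)
  }
  value
}

# NormFinder-style decomposition, recomputed longhand per gene and group.
oracle_normfinder <- function(m, groups) {
  lv <- unique(groups[colnames(m)])
  sapply(rownames(m), function(g) {
    mg <- sapply(lv, function(k) mean(m[g, groups[colnames(m)] == k]))
    vg <- sapply(lv, function(k) var(m[g, groups[colnames(m)] == k]))
    mean(abs(mg - mean(mg))) + sqrt(mean(vg))
  })
}

# Rank-aggregation index: per gene, rank pipelines ascending by the metric
# (ties averaged); index = per-pipeline median of gene ranks.
oracle_rank_index <- function(metric) {
  ranks <- matrix(NA_real_, nrow(metric), ncol(metric),
                  dimnames = dimnames(metric))
  for (g in seq_len(nrow(metric)))
    ranks[g, ] <- rank(metric[g, ], ties.method = "average")
  apply(ranks, 2, median)
}

# Brute-force UPGMA: repeatedly merge the closest pair; distance between
# clusters is the unweighted mean of member pairwise distances. Returns the
# successive merge heights and member sets.
oracle_upgma <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(rownames(d))
  heights <- numeric(0)
  members <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    heights <- c(heights, best_d)
    members[[length(members) + 1]] <- merged
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, members = members)
}

# Dunn z statistics recomputed longhand from pooled midranks and tie groups.
oracle_dunn_z <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  tie_sizes <- table(values)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  lv <- sort(unique(as.character(groups)))
  out <- c()
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (i >= j) next
    ni <- sum(groups == lv[i]); nj <- sum(groups == lv[j])
    num <- mean(r[groups == lv[i]]) - mean(r[groups == lv[j]])
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ni + 1 / nj))
    out <- c(out, setNames(num / se, paste(lv[i], lv[j], sep = "-")))
  }
  out
}

# Sorted member labels of the cluster formed at merge step i of an hclust.
hclust_members <- function(tree, i) {
  expand <- function(node)
    if (node < 0) tree$labels[-node] else
      unlist(lapply(tree$merge[node, ], expand))
  sort(unlist(lapply(tree$merge[i, ], expand)))
}

# Small complete Ct matrix -> long table with duplicate column.
ct_long_from_matrix <- function(m, duplicates = 1) {
  do.call(rbind, lapply(seq_len(duplicates), function(d)
    data.frame(gene = rep(rownames(m), ncol(m)),
               sample = rep(colnames(m), each = nrow(m)),
               duplicate = d, ct = as.vector(m),
               stringsAsFactors = FALSE)))
}

# Panels whose per-gene CoV over 3 samples equals a target value: values
# (m - m*c, m, m + m*c) have median m, MAD m*c, hence CoV c.
panel_from_cov <- function(cov_matrix) {
  genes <- rownames(cov_matrix)
  lapply(colnames(cov_matrix), function(p) {
    m <- 10
    vals <- t(sapply(genes, function(g) {
      c <- cov_matrix[g, p]
      c(m - m * c, m, m + m * c)
    }))
    colnames(vals) <- c("s1", "s2", "s3")
    make_panel(vals, p)
  }) |> setNames(colnames(cov_matrix))
}

# Minimal in-memory expression panel.
make_panel <- function(values, id = "P1", normalization = "TMM",
                       trimmer = "trimA", aligner = "alnA", counter = "cntA") {
  structure(list(values = values, pipeline_id = id, trimmer = trimmer,
                 aligner = aligner, counter = counter,
                 normalization = normalization),
            class = "expression_panel")
}
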