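#' Kruskal-Wallis rank-sum test with tie correction
#'
#' Thin, validated wrapper over [stats::kruskal.test()] (tie-corrected H,
#' chi-square p on k - 1 df), with the degenerate convention that a sample
#' in which all values are identical gives H = 0, p = 1.
#'
#' @param values numeric vector.
#' @param groups group labels, same length; >= 2 non-empty groups.
#' @return list with `H` and `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (length(values) != length(groups)) stop("length mismatch")
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("empty group")
  if (length(values) < 3) stop("need at least 3 observations")
  if (length(unique(values)) == 1) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' For every group pair (i, j):
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - sum(T)/(12(N-1))) * (1/n_i + 1/n_j))`
#' with `T = t^3 - t` per tie group of size t, mean ranks `Rbar` over the
#' pooled midranks, and two-sided p-values from the standard normal,
#' adjusted across the C(k, 2) comparisons (BH by default).
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param adjust p-adjustment method passed to [stats::p.adjust()].
#' @return list of class `group_test_result` with `H`, `p`, `groups`
#'   (data.frame: group, n, mean_rank) and `pairwise` (data.frame: group_i,
#'   group_j, z, p, p_adj).
#' @export
dunn_posthoc <- function(values, groups, adjust = "BH") {
  groups <- as.factor(as.character(groups))
  kw <- kruskal_wallis(values, groups)
  r <- rank(values, ties.method = "average")
  N <- length(values)
  lv <- levels(groups)
  n_g <- as.vector(table(groups)[lv])
  rbar <- vapply(lv, function(g) mean(r[groups == g]), numeric(1))
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(seq_along(lv), 2)
  z <- p <- numeric(ncol(pairs))
  for (c_idx in seq_len(ncol(pairs))) {
    i <- pairs[1, c_idx]; j <- pairs[2, c_idx]
    se <- sqrt(var_base * (1 / n_g[i] + 1 / n_g[j]))
    z[c_idx] <- if (se == 0) 0 else (rbar[i] - rbar[j]) / se
    p[c_idx] <- 2 * stats::pnorm(-abs(z[c_idx]))
  }
  pw <- data.frame(group_i = lv[pairs[1, ]], group_j = lv[pairs[2, ]],
                   z = z, p = p, p_adj = bh_adjust(p, method = adjust),
                   stringsAsFactors = FALSE)
  structure(list(H = kw$H, p = kw$p,
                 groups = data.frame(group = lv, n = n_g, mean_rank = rbar,
                                     stringsAsFactors = FALSE),
                 pairwise = pw),
            class = "group_test_result")
}

#' Benjamini-Hochberg (or other) multiple-testing adjustment
#'
#' Validated wrapper over [stats::p.adjust()]: step-up adjustment with
#' enforced monotonicity, capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method adjustment method, default `"BH"`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p, method = "BH") {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Min-max scale scores to the 1-100 range
#'
#' @param x numeric vector; a constant vector maps to 50.5 (midpoint).
#' @return scaled values in \[1, 100\].
#' @export
scale_1_100 <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(50.5, length(x)))
  1 + 99 * (x - rng[1]) / (rng[2] - rng[1])
}

#' Compare pipelines grouped by the algorithm used at one step
#'
#' Groups the pipelines' overall precision + accuracy scores (min-max scaled
#' to 1-100 across the included pipelines) by the algorithm label of one
#' workflow step and tests the groups with Kruskal-Wallis followed by
#' Dunn's post-hoc test. Optionally repeats the analysis after excluding
#' pipelines whose normalization label is in `exclude_normalizations`
#' (normalizations such as raw counts that bimodalize the score
#' distribution), reporting both.
#'
#' @param scores a [overall_ranking()] score table.
#' @param manifest pipeline manifest with step-label columns.
#' @param step one of `"trimmer"`, `"aligner"`, `"counter"`,
#'   `"normalization"`.
#' @param exclude_normalizations normalization labels to drop in the second
#'   pass; NULL for a single pass.
#' @param adjust p-adjustment method.
#' @return list with `all` (a `group_test_result` plus `data`) and
#'   `filtered` (same, or NULL when no exclusion is requested).
#' @export
compare_step <- function(scores, manifest, step,
                         exclude_normalizations = NULL, adjust = "BH") {
  if (!step %in% c("trimmer", "aligner", "counter", "normalization"))
    stop("unknown step: ", step)
  if (!step %in% names(manifest)) stop("manifest lacks column ", step)
  idx <- match(scores$pipeline_id, manifest$pipeline_id)
  if (anyNA(idx)) stop("pipeline(s) missing from manifest")
  df <- data.frame(pipeline_id = scores$pipeline_id,
                   overall = scores$overall,
                   label = manifest[[step]][idx],
                   normalization = manifest$normalization[idx],
                   stringsAsFactors = FALSE)
  run_one <- function(d) {
    if (length(unique(d$label)) < 2)
      stop("step ", step, " has a single label level")
    d$scaled <- scale_1_100(d$overall)
    res <- dunn_posthoc(d$scaled, d$label, adjust = adjust)
    res$data <- d
    res
  }
  out <- list(all = run_one(df), filtered = NULL)
  if (length(exclude_normalizations)) {
    keep <- !(df$normalization %in% exclude_normalizations)
    out$filtered <- run_one(df[keep, , drop = FALSE])
  }
  out
}
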