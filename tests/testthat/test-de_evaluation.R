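dct_from_matrix <- function(m) {
  data.frame(gene = rep(rownames(m), ncol(m)),
             sample = rep(colnames(m), each = nrow(m)),
             delta_ct = as.vector(m), stringsAsFactors = FALSE)
}

test_that("the DE method registry enumerates 17 methods from 11 algorithms", {
  reg <- de_method_registry()
  expect_equal(nrow(reg), 17)
  expect_equal(length(unique(reg$algorithm)), 11)
  expect_false(anyDuplicated(reg$method) > 0)
  with_variants <- table(reg$algorithm)
  expect_equal(sort(as.integer(with_variants[with_variants > 1])), c(3, 3, 3))
})

test_that("qRT-PCR truth labels come from Welch t-tests with BH adjustment", {
  m <- rbind(null = c(1, 2, 3, 1, 2, 3),
             de = c(0, 0.2, -0.1, 5, 5.2, 4.9),
             flat = rep(2, 6))
  colnames(m) <- paste0("s", 1:6)
  tl <- qpcr_de_truth(dct_from_matrix(m), paste0("s", 1:3), paste0("s", 4:6))
  # identical groups: t = 0 -> p = 1
  expect_equal(tl$raw_p[tl$gene == "null"], 1)
  # both groups constant with equal means -> p = 1
  expect_equal(tl$raw_p[tl$gene == "flat"], 1)
  expect_false(tl$label[tl$gene == "null"])
  expect_true(tl$label[tl$gene == "de"])
  # adjustment is BH across genes within the contrast
  expect_equal(tl$adj_p, bh_adjust(tl$raw_p))
  expect_error(qpcr_de_truth(dct_from_matrix(m), "s1", paste0("s", 4:6)),
               "2 samples")
})

test_that("planted delta-Ct effects are recovered with high power", {
  set.seed(99)
  runs <- 100
  n_genes <- 20; planted <- 1:5
  recovered <- total <- 0
  for (i in seq_len(runs)) {
    base <- runif(n_genes, -3, 3)
    ga <- paste0("a", 1:3); gb <- paste0("b", 1:3)
    m <- cbind(sapply(ga, function(x) base + rnorm(n_genes, 0, 0.3)),
               sapply(gb, function(x) base + rnorm(n_genes, 0, 0.3)))
    m[planted, gb] <- m[planted, gb] + 3   # 3-cycle planted shift
    rownames(m) <- sprintf("g%02d", seq_len(n_genes))
    tl <- qpcr_de_truth(dct_from_matrix(m), ga, gb, fdr = 0.05)
    recovered <- recovered +
      sum(tl$label[match(rownames(m)[planted], tl$gene)])
    total <- total + length(planted)
  }
  expect_gte(recovered / total, 0.95)   # per-gene power
})

test_that("confusion counts cross-tabulate calls against truth", {
  truth <- structure(list(gene = sprintf("g%02d", 1:10),
                          raw_p = rep(0.5, 10), adj_p = rep(0.5, 10),
                          label = rep(c(TRUE, FALSE), each = 5), fdr = 0.05),
                     class = "truth_labels")
  res <- data.frame(gene = truth$gene,
                    adj_p = c(0.01, 0.01, 0.2, 0.01, 0.6,
                              0.01, 0.3, 0.9, 0.02, 0.7))
  cnt <- confusion(res, truth, cutoff = 0.05)
  expect_equal(cnt, list(TP = 3, FP = 2, TN = 3, FN = 2))
  # perfect agreement and inverted predictions
  perfect <- data.frame(gene = truth$gene,
                        adj_p = ifelse(truth$label, 0.001, 0.999))
  expect_equal(confusion(perfect, truth)[c("FP", "FN")],
               list(FP = 0, FN = 0))
  inverted <- data.frame(gene = truth$gene,
                         adj_p = ifelse(truth$label, 0.999, 0.001))
  expect_equal(confusion(inverted, truth)[c("TP", "TN")],
               list(TP = 0, TN = 0))
  expect_error(confusion(res[1:9, ], truth), "gene sets")
})

test_that("the seven diagnostic parameters match hand computation", {
  d <- diagnostics(list(TP = 3, FP = 1, TN = 4, FN = 2))
  expect_equal(d$TPR, 0.6)
  expect_equal(d$TNR, 0.8)
  expect_equal(d$PPV, 0.75)
  expect_equal(d$NPV, 2 / 3)
  expect_equal(d$ACC, 0.7)
  expect_equal(d$MCC, 10 / sqrt(600))
  expect_equal(d$MCC, 0.4082, tolerance = 1e-3)
  # MCC conventions: 0 on zero denominator, 0 at independence, 1 when perfect
  expect_equal(diagnostics(list(TP = 0, FP = 0, TN = 5, FN = 5))$MCC, 0)
  expect_equal(diagnostics(list(TP = 4, FP = 2, TN = 2, FN = 4))$MCC, 0)
  expect_equal(diagnostics(list(TP = 5, FP = 0, TN = 5, FN = 0))$MCC, 1)
})

test_that("midrank AUC behaves as a Mann-Whitney statistic", {
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(auc_midrank(c(0.9, 0.8, 0.2, 0.1), lab), 1)
  expect_equal(auc_midrank(rep(0.5, 4), lab), 0.5)
  expect_true(is.na(auc_midrank(1:4, rep(TRUE, 4))))
  # invariant to strictly monotone transforms; agrees with pROC
  set.seed(7)
  score <- runif(40); labs <- runif(40) < 0.4
  expect_equal(auc_midrank(score, labs), auc_midrank(qnorm(score), labs))
  skip_if_not_installed("pROC")
  expect_equal(auc_midrank(score, labs),
               as.numeric(pROC::auc(pROC::roc(as.numeric(labs), score,
                                              quiet = TRUE,
                                              direction = "<"))))
})

test_that("DEG counts are monotone in the cut-off and match hand counts", {
  res <- list(
    m1 = list(c1 = data.frame(gene = paste0("g", 1:6),
                              adj_p = c(0.001, 0.004, 0.02, 0.04, 0.2, 1)),
              c2 = data.frame(gene = paste0("g", 1:6), adj_p = rep(1, 6))),
    m2 = list(c1 = data.frame(gene = paste0("g", 1:6),
                              adj_p = rep(0.0001, 6)),
              c2 = data.frame(gene = paste0("g", 1:6), adj_p = rep(1, 6))))
  cnt <- deg_counts(res)
  # the comparison is strict: adj_p = 0.001 does not count at cutoff 0.001
  expect_equal(cnt$n_deg[cnt$method == "m1" & cnt$contrast == "c1"],
               c(4, 2, 0))
  expect_true(all(cnt$n_deg[cnt$contrast == "c2"] == 0))
  for (m in names(res)) for (cc in c("c1", "c2")) {
    sub <- cnt[cnt$method == m & cnt$contrast == cc, ]
    expect_true(all(diff(sub$n_deg[order(-sub$cutoff)]) <= 0))
  }
})

test_that("method similarity clusters by Euclidean distance with UPGMA", {
  res <- list(
    A = data.frame(gene = c("g1", "g2", "g3"), adj_p = c(0.01, 0.01, 0.5)),
    B = data.frame(gene = c("g1", "g2", "g3"), adj_p = c(0.02, 0.3, 0.9)),
    C = data.frame(gene = c("g1", "g2", "g3"), adj_p = c(0.01, 0.01, 0.4)),
    D = data.frame(gene = c("g1", "g2", "g3"), adj_p = c(0.9, 0.8, 0.7)))
  sim <- method_similarity(res, cutoff = 0.05)
  dm <- as.matrix(sim$dist)
  # calls: A = (1,1,0), B = (1,0,0) -> distance 1; A = C -> 0
  expect_equal(dm["A", "B"], 1)
  expect_equal(dm["A", "C"], 0)
  expect_equal(dm["A", "D"], sqrt(2))
  # identical call vectors merge first at height 0
  expect_equal(sim$tree$height[1], 0)
  expect_true(all(diff(sim$tree$height) >= 0))
  # merge heights match the brute-force UPGMA oracle
  oracle <- oracle_upgma(sim$dist)
  expect_equal(sort(sim$tree$height), sort(oracle$heights))
  # the adjusted-p feature is exposed as an alternative
  simp <- method_similarity(res, feature = "adj_p")
  expect_gt(as.matrix(simp$dist)["A", "C"], 0)
})

test_that("UPGMA merge order matches brute force on a random instance", {
  set.seed(11)
  feat <- matrix(runif(24), 6, 4,
                 dimnames = list(paste0("m", 1:6), NULL))
  d <- dist(feat)
  tree <- hclust(d, method = "average")
  oracle <- oracle_upgma(d)
  expect_equal(tree$height, oracle$heights)
  # member sets of each merge agree
  got <- lapply(seq_len(nrow(tree$merge)), function(i)
    hclust_members(tree, i))
  expect_equal(got, oracle$members)
})

test_that("performance ranking aggregates mean metric ranks across views", {
  pars <- c("TPR", "TNR", "PPV", "NPV", "ACC", "AUC", "MCC")
  grid <- expand.grid(method = c("good", "mid", "bad"),
                      contrast = c("c1", "c2"), cutoff = c(0.05, 0.01),
                      stringsAsFactors = FALSE)
  base <- c(good = 0.9, mid = 0.6, bad = 0.3)
  for (p in pars) grid[[p]] <- base[grid$method]
  pr <- performance_rank(grid)
  expect_true(all(pr$overall$method[pr$overall$rank == 1] == "good"))
  expect_true(all(pr$by_scenario$rank[pr$by_scenario$method == "good"] == 1))
  expect_true(all(pr$by_cutoff$rank[pr$by_cutoff$method == "bad"] == 3))
  # two identical methods tie
  grid2 <- grid; grid2[grid2$method == "mid", pars] <- 0.3
  pr2 <- performance_rank(grid2)
  expect_equal(sort(pr2$overall$rank[pr2$overall$method != "good"]),
               c(2.5, 2.5))
})

test_that("an informative method dominates a noise method on MCC and AUC", {
  set.seed(55)
  runs <- 100; wins <- 0
  for (i in seq_len(runs)) {
    genes <- sprintf("g%02d", 1:40)
    label <- c(rep(TRUE, 10), rep(FALSE, 30))
    truth_p <- ifelse(label, runif(40, 1e-6, 1e-4), runif(40))
    truth <- structure(list(gene = genes, raw_p = truth_p,
                            adj_p = bh_adjust(truth_p),
                            label = label, fdr = 0.05),
                       class = "truth_labels")
    a <- data.frame(gene = genes, adj_p = bh_adjust(truth_p))
    b <- data.frame(gene = genes, adj_p = runif(40))
    da <- diagnostics(confusion(a, truth), setNames(a$adj_p, genes), truth)
    db <- diagnostics(confusion(b, truth), setNames(b$adj_p, genes), truth)
    if (da$MCC > db$MCC && da$AUC > db$AUC) wins <- wins + 1
  }
  expect_gte(wins / runs, 0.95)
})
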