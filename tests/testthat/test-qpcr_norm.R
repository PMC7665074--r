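toy_ct_matrix <- function(n_genes = 4, n_samples = 5, seed = 13) {
  set.seed(seed)
  matrix(runif(n_genes * n_samples, 20, 34), n_genes, n_samples,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("s", seq_len(n_samples))))
}

test_that("technical duplicates average arithmetically", {
  ct <- data.frame(gene = c("g1", "g1", "g2", "g3", "g3", "g3"),
                   sample = "s1", duplicate = c(1, 2, 1, 1, 2, 3),
                   ct = c(30, 32, 28.5, 30, 30, 30))
  avg <- average_duplicates(ct)
  expect_equal(avg$ct[avg$gene == "g1"], 31)
  expect_equal(avg$ct[avg$gene == "g2"], 28.5)
  expect_equal(avg$ct[avg$gene == "g3"], 30)
})

test_that("endogenous-control delta-Ct matches hand computation", {
  m <- rbind(ctrl1 = c(20, 21), ctrl2 = c(22, 23), tgt = c(25, 24))
  colnames(m) <- c("s1", "s2")
  d <- delta_ct_endogenous(m, c("ctrl1", "ctrl2"))
  # factor = mean(20, 22) = 21; dCt(tgt, s1) = 21 - 25 = -4
  expect_equal(d$delta_ct[d$gene == "tgt" & d$sample == "s1"], -4)
  expect_equal(d$delta_ct[d$gene == "tgt" & d$sample == "s2"], -2)
  # a gene normalized to itself as sole control is identically zero
  solo <- delta_ct_endogenous(m, "tgt")
  expect_true(all(solo$delta_ct[solo$gene == "tgt"] == 0))
  # full 3 x 2 hand oracle
  factor <- colMeans(m[c("ctrl1", "ctrl2"), ])
  for (g in rownames(m)) for (s in colnames(m))
    expect_equal(d$delta_ct[d$gene == g & d$sample == s],
                 unname(factor[s] - m[g, s]))
  expect_error(delta_ct_endogenous(m, "nope"), "missing")
})

test_that("global-median delta-Ct applies the strict Ct ceiling per sample", {
  m <- matrix(c(30, 32, 34), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  d <- delta_ct_global_median(m)
  expect_equal(d$delta_ct, c(2, 0, -2))
  m2 <- matrix(c(30, 35, 40), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  d2 <- delta_ct_global_median(m2)   # boundary Ct = 35 is excluded
  expect_equal(d2$delta_ct, c(0, -5, -10))
  m3 <- matrix(c(36, 37), 2, 1, dimnames = list(c("a", "b"), "sX"))
  expect_error(delta_ct_global_median(m3), "sX")
})

test_that("all delta-Ct schemes are equivariant under per-sample shifts", {
  m <- toy_ct_matrix()
  shift <- c(1.5, -2, 0.3, 4, -1)
  m2 <- sweep(m, 2, shift, `+`)
  for (fn in list(function(x) delta_ct_endogenous(x, c("g1", "g2")),
                  function(x) delta_ct_global_median(x),
                  function(x) delta_ct_most_stable(x, "g3"))) {
    a <- fn(m); b <- fn(m2)
    # between-gene differences within a sample are preserved
    am <- matrix(a$delta_ct, nrow(m)); bm <- matrix(b$delta_ct, nrow(m))
    expect_equal(apply(am, 2, diff), apply(bm, 2, diff))
  }
})

test_that("most-stable-gene delta-Ct equals endogenous with a single control", {
  m <- toy_ct_matrix()
  a <- delta_ct_most_stable(m, "g2")
  b <- delta_ct_endogenous(m, "g2")
  expect_equal(a$delta_ct, b$delta_ct)
  expect_true(all(a$delta_ct[a$gene == "g2"] == 0))
})

test_that("geNorm M matches the brute-force iterative oracle", {
  m <- toy_ct_matrix(4, 5)
  res <- stability_genorm(m)
  oracle <- oracle_genorm(m)
  expect_equal(setNames(res$value, res$gene), oracle[res$gene])
  # parallel genes have zero pairwise variation
  mp <- rbind(a = 1:6, b = (1:6) + 3, c = c(2, 5, 3, 8, 1, 4))
  colnames(mp) <- paste0("s", 1:6)
  rp <- stability_genorm(mp)
  expect_lt(rp$value[rp$gene == "a"], rp$value[rp$gene == "c"])
  # per-sample shift invariance
  shifted <- sweep(m, 2, c(5, -3, 2, 0, 1), `+`)
  expect_equal(stability_genorm(shifted)$value, res$value)
  expect_error(stability_genorm(m[1:2, ]), "3 genes")
})

test_that("comparative delta-Ct stability equals geNorm round-1 M exactly", {
  m <- toy_ct_matrix(6, 8, seed = 31)
  res <- stability_comparative_dct(m)
  expect_equal(setNames(res$value, res$gene), oracle_mean_pairwise_sd(m))
  # two genes: both stabilities equal the single pairwise SD
  m2 <- m[1:2, ]
  r2 <- stability_comparative_dct(m2)
  expect_equal(r2$value, rep(sd(m2[1, ] - m2[2, ]), 2))
})

test_that("BestKeeper ranks by Ct SD and reports index correlation", {
  m <- rbind(flat = rep(25, 4),
             g2 = c(24, 26, 25, 27),
             g3 = c(20, 30, 22, 28))
  colnames(m) <- paste0("s", 1:4)
  res <- stability_bestkeeper(m)
  expect_equal(setNames(res$value, res$gene),
               apply(m, 1, sd)[res$gene])
  expect_equal(res$rank[res$gene == "flat"], 1)
  # a gene identical to the index correlates perfectly
  idx <- colMeans(m)
  m4 <- rbind(m, asidx = idx)
  r4 <- stability_bestkeeper(m4)
  expect_gt(r4$index_cor[r4$gene == "asidx"], 0.999)
  # constant index: correlations undefined, SD ranking still works
  mc <- rbind(a = c(1, 2), b = c(2, 1), c = c(1.5, 1.5))
  colnames(mc) <- c("s1", "s2")
  rc <- stability_bestkeeper(mc)
  expect_true(all(is.na(rc$index_cor)))
  expect_equal(rc$rank[rc$gene == "c"], 1)
})

test_that("NormFinder stability matches its brute-force oracle", {
  m <- toy_ct_matrix(4, 6, seed = 77)
  groups <- setNames(rep(c("A", "B"), each = 3), colnames(m))
  res <- stability_normfinder(m, groups)
  expect_equal(setNames(res$value, res$gene), oracle_normfinder(m, groups))
  # degenerate optimum: zero intra-group variance, equal group means
  md <- rbind(perfect = rep(25, 6), m[1:2, ])
  rd <- stability_normfinder(md, groups)
  expect_equal(rd$value[rd$gene == "perfect"], 0)
  expect_equal(rd$rank[rd$gene == "perfect"], 1)
  # permuting samples within groups changes nothing
  perm <- c(2, 1, 3, 6, 4, 5)
  rp <- stability_normfinder(m[, perm], groups[colnames(m)[perm]])
  expect_equal(setNames(rp$value, rp$gene), setNames(res$value, res$gene))
  expect_error(stability_normfinder(m, setNames(rep("A", 6), colnames(m))),
               "2 groups")
})

test_that("consensus ranking is the geometric mean of method ranks", {
  mk <- function(method, ranks)
    structure(data.frame(gene = names(ranks), value = ranks, rank = ranks),
              method = method, class = c("stability_result", "data.frame"))
  genes <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4)
  res <- list(mk("genorm", c(g1 = 1, g2 = 2, g3 = 3, g4 = 4)),
              mk("normfinder", c(g1 = 1, g2 = 4, g3 = 2, g4 = 3)),
              mk("bestkeeper", c(g1 = 1, g2 = 8, g3 = 2, g4 = 3)),
              mk("comparative_dct", c(g1 = 1, g2 = 2, g3 = 4, g4 = 3)))
  cons <- consensus_rank(res)
  expect_identical(cons$most_stable, "g1")
  # g2's ranks are (2, 4, 8, 2): geometric mean = 128^(1/4)
  expect_equal(cons$table$geo_mean_rank[cons$table$gene == "g2"],
               prod(c(2, 4, 8, 2))^(1 / 4))
  # g4's ranks are (4, 3, 3, 3): geometric mean = 108^(1/4) = 3.2237...
  expect_equal(cons$table$geo_mean_rank[cons$table$gene == "g4"],
               3.2237098, tolerance = 1e-6)
  # identical rank vectors tie-break lexicographically
  res2 <- lapply(res, function(r) { r$rank <- genes; r })
  cons2 <- consensus_rank(res2)
  expect_identical(cons2$ordering, c("g1", "g2", "g3", "g4"))
  # gene-set mismatch is an error
  res3 <- res; res3[[2]] <- res3[[2]][1:3, ]
  expect_error(consensus_rank(res3), "gene set")
})

test_that("consensus recovers a planted minimal-noise gene across seeds", {
  d <- sample_sheet()
  groups <- setNames(d$cell_line, d$sample_id)
  hits <- 0; runs <- 100
  for (s in seq_len(runs)) {
    t <- generate_truth(12, d, de_fraction = 0, seed = 1000 + s)
    # noise ratio >= 3x: stable gene at sd 0.15, others 0.45
    ct <- generate_ct_table(t, noise_sd = 0.45, stable_ratio = 1 / 3,
                            seed = 1000 + s)
    stab <- list(stability_genorm(ct), stability_normfinder(ct, groups),
                 stability_bestkeeper(ct), stability_comparative_dct(ct))
    if (identical(consensus_rank(stab)$most_stable, t$stable_gene))
      hits <- hits + 1
  }
  expect_gte(hits / runs, 0.90)
})

test_that("every stability ranking is a valid permutation with average ties", {
  m <- toy_ct_matrix(5, 6, seed = 8)
  groups <- setNames(rep(c("A", "B"), each = 3), colnames(m))
  for (res in list(stability_genorm(m), stability_comparative_dct(m),
                   stability_bestkeeper(m), stability_normfinder(m, groups))) {
    expect_equal(sort(res$rank), sort(rank(res$value)))
    expect_equal(sum(res$rank), sum(seq_len(nrow(m))))
  }
})
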