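#' Build a sample sheet for a factorial cell-line x treatment design
#'
#' The default design mirrors the benchmarked study layout: two cell lines
#' (CLA, CLB), a vehicle control (T0) plus two drug treatments (T1, T2), and
#' three biological replicates per condition, i.e. 18 samples.
#'
#' @param cell_lines character vector of cell-line labels.
#' @param treatments character vector of treatment labels; the first is taken
#'   as the untreated/control level when contrasts are derived.
#' @param replicates number of biological replicates per condition.
#' @return data.frame with columns `sample_id`, `cell_line`, `treatment`,
#'   `replicate`; sample ids are `<cell_line>_<treatment>_R<replicate>`.
#' @export
sample_sheet <- function(cell_lines = c("CLA", "CLB"),
                         treatments = c("T0", "T1", "T2"),
                         replicates = 3) {
  stopifnot(length(cell_lines) >= 1, length(treatments) >= 1, replicates >= 1)
  grid <- expand.grid(
    replicate = seq_len(replicates),
    treatment = treatments,
    cell_line = cell_lines,
    stringsAsFactors = FALSE
  )[, c("cell_line", "treatment", "replicate")]
  grid$sample_id <- sprintf("%s_%s_R%d", grid$cell_line, grid$treatment,
                            grid$replicate)
  grid[, c("sample_id", "cell_line", "treatment", "replicate")]
}

#' Describe one simulated quantification pipeline
#'
#' A pipeline is a labelled combination of trimming/alignment/counting/
#' normalization algorithms plus the distortion parameters the generator uses
#' to emulate its output: a global scale factor, a per-gene multiplicative
#' bias (log2-normal with sd `bias_sd`, drawn once per pipeline), and
#' measurement noise of sd `noise_sd` on the log2 scale.
#'
#' @param pipeline_id unique identifier.
#' @param trimmer,aligner,counter,normalization algorithm labels.
#' @param scale global scale factor, must be > 0.
#' @param bias_sd sd (log2 scale) of the per-gene bias; 0 disables bias.
#' @param noise_sd sd (log2 scale) of per-observation noise; must be >= 0.
#' @return one-row data.frame (a pipeline spec).
#' @export
pipeline_spec <- function(pipeline_id, trimmer = "trimA", aligner = "alnA",
                          counter = "cntA", normalization = "normA",
                          scale = 1, bias_sd = 0, noise_sd = 0.3) {
  if (!is.numeric(scale) || scale <= 0) stop("`scale` must be > 0")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0")
  data.frame(pipeline_id = as.character(pipeline_id),
             trimmer = trimmer, aligner = aligner, counter = counter,
             normalization = normalization, scale = scale,
             bias_sd = bias_sd, noise_sd = noise_sd,
             stringsAsFactors = FALSE)
}

#' Build a factorial pipeline manifest
#'
#' Enumerates every combination of the supplied step labels (one simulated
#' pipeline each) and draws that pipeline's distortion parameters from seeded
#' distributions, so pipelines genuinely differ in noise, bias and scale.
#' The default labels give 3 x 4 x 4 x 4 = 192 pipelines, the panel size of
#' the study the generator emulates.
#'
#' @param trimmers,aligners,counters,normalizations label vectors.
#' @param noise_range range (log2 sd) from which pipeline noise is drawn.
#' @param bias_range range (log2 sd) of per-gene bias magnitude.
#' @param scale_range range of global scale factors.
#' @param seed integer RNG seed.
#' @return data.frame of pipeline specs (one row per pipeline).
#' @export
pipeline_manifest <- function(trimmers = c("Trimmomatic", "Cutadapt", "BBDuk"),
                              aligners = c("STAR", "TopHat2", "HiSat2", "RUM"),
                              counters = c("HTSeq_Union", "HTSeq_Inter",
                                           "Cufflinks", "RSEM"),
                              normalizations = c("TMM", "RLE", "TPM", "FPKM"),
                              noise_range = c(0.1, 0.8),
                              bias_range = c(0, 0.3),
                              scale_range = c(0.5, 2),
                              seed = 1L) {
  grid <- expand.grid(normalization = normalizations, counter = counters,
                      aligner = aligners, trimmer = trimmers,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("trimmer", "aligner", "counter", "normalization")]
  n <- nrow(grid)
  with_seed(seed, {
    grid$pipeline_id <- sprintf("P%03d", seq_len(n))
    grid$scale <- stats::runif(n, scale_range[1], scale_range[2])
    grid$bias_sd <- stats::runif(n, bias_range[1], bias_range[2])
    grid$noise_sd <- stats::runif(n, noise_range[1], noise_range[2])
  })
  grid[, c("pipeline_id", "trimmer", "aligner", "counter", "normalization",
           "scale", "bias_sd", "noise_sd")]
}

# Evaluate `expr` under a local, restored RNG state so generators are pure
# functions of (arguments, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic per-stage sub-seed derived from a global seed, kept inside
# the 32-bit integer range. Adding a stage never shifts another stage's
# stream.
sub_seed <- function(seed, stage) {
  offsets <- c(truth = 11L, panels = 29L, ct = 47L, de = 83L, manifest = 5L,
               candidates = 131L)
  if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
  as.integer((as.double(seed) * 7919 + offsets[[stage]]) %% .Machine$integer.max)
}

# Condition label of a sample: "<cell_line>.<treatment>".
condition_of <- function(design) paste(design$cell_line, design$treatment,
                                       sep = ".")

#' Default contrast registry for a two-line, control + treatments design
#'
#' Five contrasts: the two cell lines compared at control, and each treated
#' condition against its own line's control.
#'
#' @param design a [sample_sheet()] data.frame.
#' @param control treatment label of the untreated condition.
#' @return data.frame with columns `name`, `cond_a`, `cond_b` (condition
#'   labels `<cell_line>.<treatment>`); group A is the first-named condition.
#' @export
default_contrasts <- function(design, control = design$treatment[1]) {
  lines <- unique(design$cell_line)
  treats <- setdiff(unique(design$treatment), control)
  out <- list()
  if (length(lines) >= 2) {
    out[[1]] <- data.frame(
      name = sprintf("%s-%s_vs_%s-%s", lines[1], control, lines[2], control),
      cond_a = paste(lines[1], control, sep = "."),
      cond_b = paste(lines[2], control, sep = "."),
      stringsAsFactors = FALSE)
  }
  for (cl in lines) for (tr in treats) {
    out[[length(out) + 1]] <- data.frame(
      name = sprintf("%s-%s_vs_%s-%s", cl, tr, cl, control),
      cond_a = paste(cl, tr, sep = "."),
      cond_b = paste(cl, control, sep = "."),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a ground-truth expression model
#'
#' Plants true mean log2-expression per gene and condition, differential-
#' expression labels and effect sizes per contrast, and a designated
#' most-stable gene (which is forced non-DE so its generating variance is
#' minimal among qRT-PCR genes).
#'
#' Baseline (first condition) means are uniform on `mu_range`. For each
#' contrast, each gene is flagged DE with probability `de_fraction`; DE genes
#' receive a log2 fold-change of +/- `effect_size` (random sign), applied to
#' the contrast's group-A condition mean. Non-DE genes have identical means
#' across treatments within a cell line.
#'
#' @param n_genes number of genes (>= 2).
#' @param design a [sample_sheet()] data.frame; stored in the result so that
#'   downstream generators share the same design.
#' @param de_fraction probability a gene is DE in a given contrast.
#' @param effect_size absolute planted log2 fold-change.
#' @param seed integer RNG seed.
#' @param mu_range range of baseline mean log2-expression.
#' @return an object of class `truth_set`: list with `gene_ids`, `mu`
#'   (genes x conditions), `de_labels` and `log2fc` (genes x contrasts),
#'   `contrasts`, `stable_gene`, `design`, `seed`.
#' @export
generate_truth <- function(n_genes, design = sample_sheet(),
                           de_fraction = 0.1, effect_size = 2, seed = 1L,
                           mu_range = c(4, 12)) {
  if (!is.numeric(n_genes) || n_genes < 2) stop("`n_genes` must be >= 2")
  if (is.null(design) || nrow(design) == 0) stop("`design` is empty")
  if (de_fraction < 0 || de_fraction > 1) stop("`de_fraction` must be in [0, 1]")
  if (effect_size < 0) stop("`effect_size` must be >= 0")

  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  conds <- unique(condition_of(design))
  contrasts <- default_contrasts(design)

  with_seed(sub_seed(seed, "truth"), {
    stable_gene <- sample(gene_ids, 1)
    baseline <- stats::runif(n_genes, mu_range[1], mu_range[2])
    de <- matrix(stats::runif(n_genes * nrow(contrasts)) < de_fraction,
                 n_genes, nrow(contrasts),
                 dimnames = list(gene_ids, contrasts$name))
    sign <- matrix(sample(c(-1, 1), n_genes * nrow(contrasts), replace = TRUE),
                   n_genes, nrow(contrasts))
  })
  de[match(stable_gene, gene_ids), ] <- FALSE
  log2fc <- ifelse(de, sign * effect_size, 0)
  dimnames(log2fc) <- dimnames(de)

  # Control conditions carry the baseline; the cross-line control contrast
  # and the within-line treatment contrasts shift the group-A condition.
  mu <- matrix(baseline, n_genes, length(conds),
               dimnames = list(gene_ids, conds))
  for (i in seq_len(nrow(contrasts))) {
    mu[, contrasts$cond_a[i]] <- mu[, contrasts$cond_b[i]] + log2fc[, i]
  }

  structure(list(gene_ids = gene_ids, mu = mu, de_labels = de,
                 log2fc = log2fc, contrasts = contrasts,
                 stable_gene = stable_gene, design = design,
                 seed = as.integer(seed)),
            class = "truth_set")
}

#' Generate expression panels for a manifest of simulated pipelines
#'
#' For pipeline p, sample s and gene g the simulated value is
#' `scale_p * bias_p(g) * 2^(mu[g, condition(s)] + eps)` with
#' `eps ~ N(0, noise_sd_p)` on the log2 scale and `bias_p(g) = 2^N(0, bias_sd_p)`
#' drawn once per pipeline. All values are strictly positive.
#'
#' @param truth a [generate_truth()] result.
#' @param manifest data.frame of pipeline specs ([pipeline_manifest()]).
#' @param design sample sheet; defaults to the one stored in `truth`.
#' @param seed integer RNG seed.
#' @return named list of `expression_panel` objects (one per pipeline), each
#'   a list with `values` (genes x samples matrix), `pipeline_id` and the
#'   step labels.
#' @export
generate_panels <- function(truth, manifest, design = truth$design, seed = 1L) {
  stopifnot(inherits(truth, "truth_set"))
  if (is.null(manifest) || nrow(manifest) == 0) stop("`manifest` is empty")
  if (any(manifest$noise_sd < 0)) stop("pipeline `noise_sd` must be >= 0")
  if (any(manifest$scale <= 0)) stop("pipeline `scale` must be > 0")
  if (anyDuplicated(manifest$pipeline_id))
    stop("duplicate `pipeline_id` in manifest")
  conds <- condition_of(design)
  if (!all(conds %in% colnames(truth$mu)))
    stop("unknown sample condition: ",
         paste(setdiff(conds, colnames(truth$mu)), collapse = ", "))

  mu_s <- truth$mu[, conds, drop = FALSE]  # genes x samples
  colnames(mu_s) <- design$sample_id
  n_g <- length(truth$gene_ids); n_s <- nrow(design)

  with_seed(sub_seed(seed, "panels"), {
    panels <- lapply(seq_len(nrow(manifest)), function(i) {
      p <- manifest[i, ]
      bias <- 2^stats::rnorm(n_g, 0, p$bias_sd)
      eps <- matrix(stats::rnorm(n_g * n_s, 0, p$noise_sd), n_g, n_s)
      values <- p$scale * bias * 2^(mu_s + eps)
      dimnames(values) <- list(truth$gene_ids, design$sample_id)
      structure(list(values = values, pipeline_id = p$pipeline_id,
                     trimmer = p$trimmer, aligner = p$aligner,
                     counter = p$counter, normalization = p$normalization),
                class = "expression_panel")
    })
  })
  names(panels) <- manifest$pipeline_id
  panels
}

#' Generate a qRT-PCR cycle-threshold table
#'
#' Ct is inversely linear in true log2-expression:
#' `Ct[g, s, d] = alpha - beta * (mu[g, condition(s)] + eps)` with
#' `eps ~ N(0, sd_g)` drawn independently per (gene, sample, duplicate).
#' The planted most-stable gene receives `noise_sd * stable_ratio`, the
#' smallest noise in the table; all other genes receive `noise_sd`.
#'
#' @param truth a [generate_truth()] result.
#' @param genes subset of `truth$gene_ids` to assay.
#' @param alpha intercept (cycles); default 38 keeps Ct in a realistic range.
#' @param beta slope in cycles per log2 unit; must be > 0.
#' @param noise_sd measurement noise sd (cycles / beta on the mu scale).
#' @param n_duplicates technical duplicates per (gene, sample); >= 1.
#' @param stable_ratio noise multiplier for the stable gene (< 1).
#' @param design sample sheet; defaults to the one stored in `truth`.
#' @param seed integer RNG seed.
#' @return data.frame (long format) with columns `gene`, `sample`,
#'   `duplicate`, `ct`.
#' @export
generate_ct_table <- function(truth, genes = truth$gene_ids, alpha = 38,
                              beta = 1, noise_sd = 0.25, n_duplicates = 2,
                              stable_ratio = 0.25, design = truth$design,
                              seed = 1L) {
  stopifnot(inherits(truth, "truth_set"))
  if (beta <= 0) stop("`beta` must be > 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (n_duplicates < 1) stop("`n_duplicates` must be >= 1")
  if (!all(genes %in% truth$gene_ids))
    stop("`genes` must be a subset of the truth gene ids")

  conds <- condition_of(design)
  sd_g <- stats::setNames(rep(noise_sd, length(genes)), genes)
  if (truth$stable_gene %in% genes)
    sd_g[truth$stable_gene] <- noise_sd * stable_ratio

  out <- expand.grid(duplicate = seq_len(n_duplicates),
                     sample = design$sample_id, gene = genes,
                     stringsAsFactors = FALSE)[, c("gene", "sample", "duplicate")]
  cond <- conds[match(out$sample, design$sample_id)]
  mu <- truth$mu[cbind(out$gene, cond)]
  with_seed(sub_seed(seed, "ct"), {
    eps <- stats::rnorm(nrow(out), 0, sd_g[out$gene])
  })
  out$ct <- alpha - beta * (mu + eps)
  rownames(out) <- NULL
  out
}

#' Generate synthetic differential-expression result tables
#'
#' Stand-ins for the outputs of external DE methods, for exercising the
#' evaluation stage. Each method re-tests the true per-gene group means with
#' method-specific perturbation: a method of quality `q` reports p-values
#' from a Welch t-test on noisy copies of the true means (noise sd scales
#' with `1 - q`), BH-adjusted within each contrast. `q = 1` reproduces the
#' truth-generating test closely; `q = 0` is uninformative.
#'
#' @param truth a [generate_truth()] result.
#' @param methods character vector of method labels.
#' @param quality named numeric in \[0, 1\] per method; defaults to equally
#'   spaced qualities.
#' @param noise_sd sd (log2 scale) of the expression noise the simulated
#'   methods observe; the default 0.3 matches the generator's qRT-PCR-scale
#'   biological variability, so method qualities span the detection range
#'   (the best methods recover most planted effects after BH adjustment,
#'   the worst recover few).
#' @param n_rep replicates per condition each simulated method observes.
#' @param seed integer RNG seed.
#' @return named list (method) of named lists (contrast) of data.frames with
#'   columns `gene`, `raw_p`, `adj_p`.
#' @export
synthetic_de_results <- function(truth, methods,
                                 quality = NULL, noise_sd = 0.3, n_rep = 3,
                                 seed = 1L) {
  stopifnot(inherits(truth, "truth_set"))
  if (is.null(quality))
    quality <- stats::setNames(seq(1, 0.3, length.out = length(methods)),
                               methods)
  with_seed(sub_seed(seed, "de"), {
    res <- lapply(methods, function(m) {
      q <- quality[[m]]
      per_contrast <- lapply(seq_len(nrow(truth$contrasts)), function(i) {
        ca <- truth$contrasts$cond_a[i]; cb <- truth$contrasts$cond_b[i]
        sd_m <- noise_sd * (1 + 3 * (1 - q))
        p <- vapply(seq_along(truth$gene_ids), function(g) {
          a <- stats::rnorm(n_rep, truth$mu[g, ca], sd_m)
          b <- stats::rnorm(n_rep, truth$mu[g, cb], sd_m)
          welch_p(a, b)
        }, numeric(1))
        data.frame(gene = truth$gene_ids, raw_p = p,
                   adj_p = stats::p.adjust(p, "BH"),
                   stringsAsFactors = FALSE)
      })
      names(per_contrast) <- truth$contrasts$name
      per_contrast
    })
  })
  names(res) <- methods
  res
}

# Welch t-test p-value with the degenerate-variance convention: both groups
# constant -> 1 if the means agree, else 0.
welch_p <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  stats::t.test(a, b)$p.value
}
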