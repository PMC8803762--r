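# Differential-expression screening of NLR genes and time-point clustering
# of infection courses.

#' DEG screening criteria
#'
#' The defaults are the conjunctive thresholds used throughout:
#' |logFC| >= 2 (inclusive), p < 0.05 and FDR < 0.05 (both exclusive).
#'
#' @param min_abs_logfc Minimum absolute log2 fold change (>=).
#' @param max_p p-value bound (strict <).
#' @param max_fdr FDR bound (strict <).
#' @export
deg_criteria <- function(min_abs_logfc = 2, max_p = 0.05, max_fdr = 0.05) {
  list(min_abs_logfc = min_abs_logfc, max_p = max_p, max_fdr = max_fdr)
}

#' Screen a DE table for differentially expressed genes
#'
#' Applies the criteria conjunctively. Boundary semantics: |logFC| equal to
#' the threshold passes; p or FDR equal to their bounds fail.
#'
#' @param deg_table Data frame with columns `gene_id`, `logFC`, `p` (or
#'   `pvalue`/`p_value`/`P`) and `FDR`.
#' @param criteria A [deg_criteria()] list.
#' @return Sorted character vector of passing gene ids.
#' @export
screen_degs <- function(deg_table, criteria = deg_criteria()) {
  nm <- names(deg_table)
  pick <- function(cands, what) {
    hit <- nm[tolower(nm) %in% tolower(cands)]
    if (length(hit) == 0) stop("DE table is missing the ", what, " column")
    hit[1]
  }
  gcol <- pick("gene_id", "gene_id")
  fcol <- pick(c("logFC", "log_fc", "logfc"), "logFC")
  pcol <- pick(c("p", "pvalue", "p_value", "pval"), "p-value")
  qcol <- pick(c("FDR", "padj", "qvalue"), "FDR")
  keep <- abs(deg_table[[fcol]]) >= criteria$min_abs_logfc &
    deg_table[[pcol]] < criteria$max_p &
    deg_table[[qcol]] < criteria$max_fdr
  keep[is.na(keep)] <- FALSE
  sort(unique(deg_table[[gcol]][keep]))
}

#' Cluster time-point samples of one genotype
#'
#' Hierarchical clustering of samples on log2(FPKM + 1) gene profiles with
#' correlation distance (1 - Pearson) and average linkage; constant gene
#' rows are dropped with a warning before the correlation. Returns the full
#' dendrogram and the flat two-group cut.
#'
#' @param fpkm Gene x sample numeric matrix (FPKM, >= 0).
#' @param meta Optional sample metadata (`sample_id`, `genotype`,
#'   `timepoint_h`) used to subset to one genotype.
#' @param genotype Genotype to keep when `meta` is given.
#' @param k Number of flat groups to cut (default 2).
#' @return List with `hclust`, `groups` (named integer vector) and
#'   `dropped_genes`.
#' @export
cluster_timepoints <- function(fpkm, meta = NULL, genotype = NULL, k = 2) {
  if (!is.null(meta) && !is.null(genotype)) {
    keep <- meta$sample_id[meta$genotype == genotype]
    if (length(keep) == 0) stop("no samples for genotype ", genotype)
    fpkm <- fpkm[, keep, drop = FALSE]
  }
  if (ncol(fpkm) < 3) stop("need at least 3 samples to cluster")
  lm2 <- log2(fpkm + 1)
  const <- apply(lm2, 1, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " constant gene row(s) dropped before correlation")
    lm2 <- lm2[!const, , drop = FALSE]
  }
  if (nrow(lm2) < 2) stop("fewer than 2 variable genes left")
  d <- stats::as.dist(1 - stats::cor(lm2))
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, groups = stats::cutree(hc, k = k),
       dropped_genes = names(const)[const])
}

#' Early/late expression contrast between genotypes
#'
#' Splits the time course into early (`<= early_max` hours) and late
#' (`>= late_min` hours) windows, reports per-gene and aggregate mean FPKM
#' per window and genotype, and a per-gene Welch test of resistant versus
#' susceptible levels plus one aggregate Welch test on the sample means.
#'
#' @param fpkm Gene x sample matrix.
#' @param meta Sample metadata (`sample_id`, `genotype`, `timepoint_h`);
#'   both genotypes must be present.
#' @param early_max,late_min Window boundaries in hours (defaults 12 / 24).
#' @return List with `per_gene` (data frame), `aggregate` (data frame of
#'   early/late means per genotype) and `aggregate_p`.
#' @export
genotype_contrast <- function(fpkm, meta, early_max = 12, late_min = 24) {
  genos <- unique(meta$genotype)
  if (!all(c("resistant", "susceptible") %in% genos)) {
    stop("need both resistant and susceptible genotypes")
  }
  cols <- function(geno, window) {
    tp <- meta$timepoint_h
    keep <- meta$genotype == geno &
      if (window == "early") tp <= early_max else tp >= late_min
    meta$sample_id[keep]
  }
  mean_block <- function(geno, window) {
    rowMeans(fpkm[, cols(geno, window), drop = FALSE])
  }
  per_gene <- data.frame(
    gene_id = rownames(fpkm),
    early_resistant = mean_block("resistant", "early"),
    late_resistant = mean_block("resistant", "late"),
    early_susceptible = mean_block("susceptible", "early"),
    late_susceptible = mean_block("susceptible", "late"),
    row.names = NULL)
  rcols <- meta$sample_id[meta$genotype == "resistant"]
  scols <- meta$sample_id[meta$genotype == "susceptible"]
  per_gene$p <- vapply(seq_len(nrow(fpkm)), function(i) {
    a <- fpkm[i, rcols]
    b <- fpkm[i, scols]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    }
    stats::t.test(a, b)$p.value
  }, numeric(1))
  aggregate <- do.call(rbind, lapply(c("resistant", "susceptible"), function(g) {
    data.frame(genotype = g,
               early_mean = mean(fpkm[, cols(g, "early"), drop = FALSE]),
               late_mean = mean(fpkm[, cols(g, "late"), drop = FALSE]))
  }))
  ra <- colMeans(fpkm[, rcols, drop = FALSE])
  sa <- colMeans(fpkm[, scols, drop = FALSE])
  aggregate_p <- if (stats::var(ra) == 0 && stats::var(sa) == 0 &&
                     isTRUE(all.equal(mean(ra), mean(sa)))) 1
  else stats::t.test(ra, sa)$p.value
  list(per_gene = per_gene, aggregate = aggregate, aggregate_p = aggregate_p)
}
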