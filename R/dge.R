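#' Median-based log2 fold change between two groups
#'
#' For each gene, the group medians of normalized expression are taken
#' and the fold change is `log2(median_A) - log2(median_B)`. When either
#' median is zero a pseudocount is added to both before taking logs.
#'
#' @param values Genes x samples matrix of normalized expression.
#' @param groups Character vector of group labels per sample.
#' @param group_a,group_b Compared groups (A over B).
#' @param pseudocount Added to both medians only when one is zero.
#' @return Named per-gene log2 fold change.
#' @export
median_log2fc <- function(values, groups, group_a, group_b,
                          pseudocount = 0.5) {
  a <- values[, groups == group_a, drop = FALSE]
  b <- values[, groups == group_b, drop = FALSE]
  if (ncol(a) == 0L || ncol(b) == 0L)
    stop("empty group in comparison ", group_a, " vs ", group_b)
  med_a <- apply(a, 1, stats::median)
  med_b <- apply(b, 1, stats::median)
  zero <- med_a == 0 | med_b == 0
  med_a[zero] <- med_a[zero] + pseudocount
  med_b[zero] <- med_b[zero] + pseudocount
  log2(med_a) - log2(med_b)
}

#' Per-gene two-sided Wilcoxon rank-sum p-values
#'
#' Exact enumeration is used when the smaller group has at most
#' `exact_limit` samples and the gene has no ties; otherwise the
#' tie-corrected normal approximation with continuity correction. A gene
#' constant across both groups carries no rank information and is
#' reported as p = 1.
#'
#' @param values Genes x samples matrix.
#' @param groups Group labels per sample.
#' @param group_a,group_b Compared groups (each with >= 2 samples).
#' @param exact_limit Largest min-group size for the exact test.
#' @return Named per-gene p-value vector.
#' @export
wilcoxon_de <- function(values, groups, group_a, group_b,
                        exact_limit = 12L) {
  a_idx <- which(groups == group_a)
  b_idx <- which(groups == group_b)
  if (length(a_idx) < 2L || length(b_idx) < 2L)
    stop("each group needs at least 2 samples")
  use_exact <- min(length(a_idx), length(b_idx)) <= exact_limit
  apply(values, 1, function(v) {
    x <- v[a_idx]; y <- v[b_idx]
    if (stats::sd(c(x, y)) == 0) return(1)
    ties <- anyDuplicated(c(x, y)) > 0L
    suppressWarnings(stats::wilcox.test(
      x, y, alternative = "two.sided",
      exact = use_exact && !ties, correct = TRUE)$p.value)
  })
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up adjustment with the harmonic correction
#' `c(m) = sum(1/i, i = 1..m)`, valid under arbitrary dependence between
#' tests. Wraps the standard implementation.
#'
#' @param p Raw p-values.
#' @return Adjusted p-values in input order.
#' @export
adjust_by <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BY")
}

#' Pairwise differential-expression table
#'
#' @param norm A `content_normalized` [count_matrix()] (or any
#'   genes x samples matrix plus `groups`).
#' @param group_a,group_b Compared diagnosis groups (A over B).
#' @param groups Group labels (defaults to the matrix's `diagnosis`).
#' @param alpha Significance level on the adjusted p-value.
#' @param endogenous_only Restrict to endogenous probes (default).
#' @return A `dge_table` data.frame sorted by adjusted p ascending (ties
#'   by `|log2fc|` descending, then gene symbol) with columns
#'   `probe_id`, `gene`, `median_a`, `median_b`, `log2fc`, `p_raw`,
#'   `fdr_p`, `significant`.
#' @export
dge_table <- function(norm, group_a, group_b, groups = NULL,
                      alpha = 0.05, endogenous_only = TRUE) {
  if (inherits(norm, "count_matrix")) {
    groups <- groups %||% norm$samples$diagnosis
    ids <- if (endogenous_only) matrix_rows(norm, "Endogenous")
           else rownames(norm$values)
    values <- norm$values[ids, , drop = FALSE]
    symbols <- norm$panel$probes$gene_symbol[
      match(ids, norm$panel$probes$probe_id)]
  } else {
    stopifnot(is.matrix(norm), !is.null(groups))
    values <- norm
    ids <- rownames(values)
    symbols <- ids
  }
  lfc <- median_log2fc(values, groups, group_a, group_b)
  med_a <- apply(values[, groups == group_a, drop = FALSE], 1,
                 stats::median)
  med_b <- apply(values[, groups == group_b, drop = FALSE], 1,
                 stats::median)
  p <- wilcoxon_de(values, groups, group_a, group_b)
  q <- adjust_by(p)
  tab <- data.frame(
    probe_id = ids, gene = symbols,
    median_a = unname(med_a), median_b = unname(med_b),
    log2fc = unname(lfc), p_raw = unname(p), fdr_p = unname(q),
    significant = unname(q < alpha),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$fdr_p, -abs(tab$log2fc), tab$gene), ]
  rownames(tab) <- NULL
  attr(tab, "comparison") <- c(group_a, group_b)
  attr(tab, "alpha") <- alpha
  class(tab) <- c("dge_table", "data.frame")
  tab
}

#' Top differentially expressed genes
#'
#' The `k` genes with smallest adjusted p-value; ties broken by absolute
#' log2 fold change (descending), then gene symbol.
#'
#' @param table A [dge_table()].
#' @param k Number of genes (default 20).
#' @return Character vector of gene symbols.
#' @export
top_degs <- function(table, k = 20L) {
  if (k > nrow(table)) {
    warning("k exceeds the number of genes; returning all")
    k <- nrow(table)
  }
  table$gene[seq_len(k)]
}

#' Cross-panel correlation of top-gene fold changes
#'
#' Pearson correlation of the log2 fold changes of the union of both
#' tables' top-`k` genes, restricted to genes shared by both panels.
#' Mirrors a retest-reliability comparison of two panels assaying the
#' same cohort.
#'
#' @param table_a,table_b [dge_table()]s for the same comparison.
#' @param shared_genes Gene symbols present on both panels (defaults to
#'   the intersection of the tables' genes).
#' @param k Top-list size per table (default 20).
#' @return Pearson correlation coefficient.
#' @export
retest_correlation <- function(table_a, table_b, shared_genes = NULL,
                               k = 20L) {
  shared_genes <- shared_genes %||% intersect(table_a$gene, table_b$gene)
  top <- union(top_degs(table_a, min(k, nrow(table_a))),
               top_degs(table_b, min(k, nrow(table_b))))
  top <- intersect(top, shared_genes)
  if (length(top) < 3L)
    stop("fewer than 3 shared genes among the top lists")
  a <- table_a$log2fc[match(top, table_a$gene)]
  b <- table_b$log2fc[match(top, table_b$gene)]
  stats::cor(a, b, method = "pearson")
}

#' Volcano-plot coordinates
#'
#' @param table A [dge_table()].
#' @return data.frame of `gene`, `log2fc` and `neg_log10_fdr_p`.
#' @export
volcano_data <- function(table) {
  data.frame(gene = table$gene, log2fc = table$log2fc,
             neg_log10_fdr_p = -log10(pmax(table$fdr_p, 1e-300)),
             stringsAsFactors = FALSE)
}
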