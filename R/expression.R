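#' Tau tissue-specificity index
#'
#' `tau = sum_i (1 - x_i / max(x)) / (N - 1)` over `N` tissues: 0 for a
#' uniformly expressed gene, 1 for expression confined to a single tissue.
#' The index is invariant to rescaling the whole vector.
#'
#' @param x non-negative expression vector over at least two tissues.
#' @return tau in `[0, 1]`; `NA` (with a warning) for an all-zero vector,
#'   for which the index is undefined and the gene should be excluded.
#' @export
#' @examples
#' tau(c(5, 0, 0, 0, 0))       # 1
#' tau(c(3, 3, 3, 3, 3))       # 0
#' tau(c(1, 0.5, 0, 0, 0))     # 0.875
tau <- function(x) {
  if (length(x) < 2) stop("tau needs at least two tissues")
  if (any(x < 0, na.rm = TRUE)) stop("negative expression values")
  m <- max(x)
  if (!is.finite(m) || m <= 0) {
    warning("all-zero expression vector: tau undefined")
    return(NA_real_)
  }
  sum(1 - x / m) / (length(x) - 1)
}

#' Per-gene tau, tissue assignment and expression level
#'
#' Computes tau for every row of an expression matrix, assigns each gene to
#' its arg-max tissue and records the expression level in that tissue. Genes
#' with an undefined tau (all-zero rows) are dropped with a warning.
#'
#' @param mat genes x tissues matrix (rownames = genes).
#' @return data frame `gene, tau, tissue, level`.
#' @export
tau_table <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  tv <- suppressWarnings(apply(mat, 1, tau))
  keep <- !is.na(tv)
  if (any(!keep)) warning(sum(!keep), " gene(s) with all-zero expression dropped")
  j <- apply(mat[keep, , drop = FALSE], 1, which.max)
  data.frame(gene = rownames(mat)[keep], tau = unname(tv[keep]),
             tissue = colnames(mat)[j],
             level = mat[keep, , drop = FALSE][cbind(seq_len(sum(keep)), j)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tissue-specific gene sets
#'
#' Genes with `tau >= tau_min` are assigned to the set of their arg-max
#' tissue; the `all_genes` set contains every gene regardless of expression
#' pattern.
#'
#' @param tt a [tau_table()].
#' @param tau_min specificity threshold (default 0.8, inclusive).
#' @return named list of gene-id vectors: one per tissue plus `all_genes`.
#' @export
select_tissue_specific <- function(tt, tau_min = 0.8) {
  spec <- tt[tt$tau >= tau_min, , drop = FALSE]
  sets <- split(spec$gene, spec$tissue)
  sets <- sets[order(names(sets))]
  c(sets, list(all_genes = tt$gene))
}

#' Restrict a gene set to the genes above its median tau
#'
#' @param tt a [tau_table()].
#' @param genes gene ids of the set (>= 2 genes).
#' @return gene ids with tau strictly greater than the within-set median.
#' @export
subset_high_tau <- function(tt, genes) {
  sel <- tt[tt$gene %in% genes, , drop = FALSE]
  if (nrow(sel) < 2) stop("need at least two genes")
  sel$gene[sel$tau > median(sel$tau)]
}

#' Restrict a gene set to its low-expression half
#'
#' Keeps genes whose expression level (value in the assigned tissue) ranges
#' from the lowest value up to and including the within-set median.
#'
#' @inheritParams subset_high_tau
#' @return gene ids with level <= within-set median level.
#' @export
subset_low_expression <- function(tt, genes) {
  sel <- tt[tt$gene %in% genes, , drop = FALSE]
  if (nrow(sel) < 2) stop("need at least two genes")
  sel$gene[sel$level <= median(sel$level)]
}
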