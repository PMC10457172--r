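#' Simulate a genes x tissues expression matrix with known tau
#'
#' Each gene gets its ground-truth expression level in its assigned tissue
#' and a jittered fraction of that level elsewhere, constructed so that the
#' tau tissue-specificity index of the emitted vector equals the gene's true
#' tau exactly (up to floating point): with maximum expression `L` and target
#' tau `t`, the remaining tissues receive `L * (1 - t) * w` with jitter
#' weights `w` of mean 1, bounded so the assigned tissue stays the maximum.
#'
#' @param config a [sim_config()].
#' @param truth a [ground_truth()]; supplies per-gene tau (must lie in
#'   `[0, 1]`), tissue assignment and the master seed via `config`.
#' @return numeric matrix (genes x tissues) with dimnames, TMM-like units.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 5, seed = 2)
#' mat <- simulate_expression(cfg, ground_truth(cfg))
#' apply(mat, 1, tau)
simulate_expression <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  if (config$n_tissues < 2) stop("need at least two tissues")
  if (any(truth$tau < 0 | truth$tau > 1))
    stop("target tau outside [0, 1]")
  g <- config$n_genes
  nt <- config$n_tissues
  with_seed(derive_seed(config$seed, 41), {
    level <- rlnorm(g, config$expr_level_meanlog, config$expr_level_sdlog)
    mat <- matrix(0, g, nt, dimnames = list(truth$gene, config$tissue_names))
    for (i in seq_len(g)) {
      t_i <- truth$tau[i]
      rest <- 1 - t_i
      u <- runif(nt - 1, -1, 1)
      u <- u - mean(u)                      # jitter with exact mean zero
      amp <- 0.4
      if (rest > 0) {
        # keep every off-tissue value strictly below the assigned tissue
        cap <- 0.9 * (1 / rest - 1) / max(abs(u), 1e-12)
        amp <- min(amp, cap)
      }
      w <- 1 + amp * u
      x <- level[i] * rest * w
      j <- match(truth$tissue[i], config$tissue_names)
      mat[i, -j] <- x
      mat[i, j] <- level[i]
    }
    mat
  })
}

#' Write an expression matrix as TSV (genes in rows, tissues in columns)
#' @param mat matrix from [simulate_expression()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression()]
#' @param path TSV with a `gene` column and one column per tissue.
#' @return numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene
  mat
}
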