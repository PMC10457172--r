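#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data module. Defaults emulate the study
#' conditions the pipeline is designed for: 20 haploid samples from one
#' panmictic population, a per-site scaled mutation rate of 0.005 (the value
#' also used as the variant-caller prior), five tissues (one haploid, four
#' diploid), and at most 20\% missing genotypes.
#'
#' @param n_samples number of haploid samples (cohort size).
#' @param n_genes number of genes (one gene per contig).
#' @param gene_length CDS length in bp, a multiple of 3 (includes the
#'   terminal stop codon).
#' @param flank non-coding flank on each side of the CDS, in bp.
#' @param n_tissues number of tissues in the expression matrix.
#' @param tissue_names tissue labels; the first is the haploid tissue.
#' @param theta_pop per-site scaled mutation rate used to seed variant density.
#' @param paralog_fraction fraction of genes simulated as collapsed paralogs.
#' @param paralog_divergence per-bp divergence between collapsed copies.
#' @param missing_rate per-genotype missing probability (must be in `[0, 1]`;
#'   the emulated study design keeps it at or below 0.2).
#' @param depth_mean mean per-genotype read depth (DP); DP is drawn from a
#'   negative binomial with this mean.
#' @param depth_size negative-binomial size (overdispersion) for DP.
#' @param gq_mean mean genotype quality (GQ); GQ is 1 plus a Poisson draw.
#' @param minus_strand_fraction fraction of genes placed on the minus strand.
#' @param prop_specific fraction of genes simulated with tau >= 0.8.
#' @param expr_level_meanlog,expr_level_sdlog log-normal parameters of the
#'   expression level in the assigned tissue (TMM-like units).
#' @param seed master seed; all generators derive child streams from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 10, seed = 7)
sim_config <- function(n_samples = 20,
                       n_genes = 60,
                       gene_length = 300,
                       flank = 60,
                       n_tissues = 5,
                       tissue_names = c("megagametophyte", "bud", "embryo",
                                        "needle", "phloem"),
                       theta_pop = 0.005,
                       paralog_fraction = 0.1,
                       paralog_divergence = 0.02,
                       missing_rate = 0.1,
                       depth_mean = 30,
                       depth_size = 5,
                       gq_mean = 60,
                       minus_strand_fraction = 0.5,
                       prop_specific = 0.6,
                       expr_level_meanlog = log(10),
                       expr_level_sdlog = 1,
                       seed = 1L) {
  if (n_tissues != length(tissue_names))
    tissue_names <- paste0("tissue", seq_len(n_tissues))
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length), flank = as.integer(flank),
              n_tissues = as.integer(n_tissues), tissue_names = tissue_names,
              theta_pop = theta_pop, paralog_fraction = paralog_fraction,
              paralog_divergence = paralog_divergence,
              missing_rate = missing_rate, depth_mean = depth_mean,
              depth_size = depth_size, gq_mean = gq_mean,
              minus_strand_fraction = minus_strand_fraction,
              prop_specific = prop_specific,
              expr_level_meanlog = expr_level_meanlog,
              expr_level_sdlog = expr_level_sdlog, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_samples >= 2, cfg$n_genes >= 1,
            cfg$gene_length >= 3, cfg$gene_length %% 3 == 0,
            cfg$flank >= 0, cfg$n_tissues >= 2)
  if (cfg$theta_pop <= 0) stop("theta_pop must be > 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1)
    stop("missing_rate must be in [0, 1]")
  if (cfg$paralog_fraction < 0 || cfg$paralog_fraction > 1)
    stop("paralog_fraction must be in [0, 1]")
  if (cfg$minus_strand_fraction < 0 || cfg$minus_strand_fraction > 1)
    stop("minus_strand_fraction must be in [0, 1]")
  invisible(cfg)
}

#' Ground truth for a synthetic data set
#'
#' Fixes the quantities the pipeline later tries to recover: the gamma
#' distribution of deleterious fitness effects (shape `beta`, mean effect
#' magnitude `Es`), the two-epoch demography (post-change relative size
#' `N2_ratio` for `t2` generations), per-gene target tau values and tissue
#' assignments, and which genes are collapsed paralogs.
#'
#' @param config a [sim_config()].
#' @param beta gamma shape of the deleterious DFE (> 0).
#' @param Es mean magnitude of the deleterious effect (> 0).
#' @param N2_ratio post-change population size relative to the ancestral
#'   size (> 0); 1 means equilibrium.
#' @param t2 duration of the post-change epoch in generations (>= 0).
#' @return an object of class `ground_truth` with per-gene `tau`, `tissue`,
#'   `paralog` flags and the demographic/DFE parameters.
#' @export
ground_truth <- function(config, beta = 0.5, Es = 0.1,
                         N2_ratio = 1, t2 = 0) {
  stopifnot(inherits(config, "sim_config"))
  if (beta <= 0) stop("beta must be > 0")
  if (Es <= 0) stop("Es must be > 0")
  if (N2_ratio <= 0) stop("N2_ratio must be > 0")
  if (t2 < 0) stop("t2 must be >= 0")
  g <- config$n_genes
  with_seed(derive_seed(config$seed, 11), {
    n_spec <- round(config$prop_specific * g)
    tau <- c(runif(n_spec, 0.8, 1), runif(g - n_spec, 0, 0.8))[sample.int(g)]
    tissue <- sample(config$tissue_names, g, replace = TRUE)
    paralog <- rep(FALSE, g)
    n_par <- round(config$paralog_fraction * g)
    if (n_par > 0) paralog[sample.int(g, n_par)] <- TRUE
    structure(list(beta = beta, Es = Es, N2_ratio = N2_ratio, t2 = t2,
                   tau = tau, tissue = tissue, paralog = paralog,
                   gene = gene_ids(g)),
              class = "ground_truth")
  })
}

gene_ids <- function(n) sprintf("gene%04d", seq_len(n))

#' @export
print.sim_config <- function(x, ...) {
  cat("synthetic-data configuration\n")
  cat(sprintf("  %d haploid samples, %d genes x (%d bp CDS + 2x%d bp flank)\n",
              x$n_samples, x$n_genes, x$gene_length, x$flank))
  cat(sprintf("  theta = %g, paralog fraction = %g, missing rate = %g\n",
              x$theta_pop, x$paralog_fraction, x$missing_rate))
  cat(sprintf("  tissues: %s\n", paste(x$tissue_names, collapse = ", ")))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground truth: beta = %g, E(s) = %g, N2/N1 = %g, t2 = %g\n",
              x$beta, x$Es, x$N2_ratio, x$t2))
  cat(sprintf("  %d genes (%d tissue-specific at tau >= 0.8, %d paralogous)\n",
              length(x$tau), sum(x$tau >= 0.8), sum(x$paralog)))
  invisible(x)
}
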