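#' Simulate a dual-ploidy call set for a haploid cohort
#'
#' Emulates calling the same haploid samples twice, once in haploid mode and
#' once in diploid mode. Non-coding, 2-fold, 3-fold and 4-fold positions
#' segregate at frequencies drawn from the neutral (or two-epoch) expected
#' spectrum at density set by `theta_pop`; 0-fold coding positions segregate
#' under the ground-truth gamma DFE, which both thins them and skews them
#' towards rare alleles, so the downstream diversity and DFE contrasts have
#' a known answer. Per-genotype depth is negative binomial and genotype quality a shifted
#' Poisson; genotypes go missing independently at `missing_rate`. Genes
#' flagged as paralogs in the ground truth get collapsed-duplicate sites:
#' in the diploid-mode call every non-missing sample is heterozygous there,
#' while the haploid-mode caller picks one of the two copies at random.
#' Non-paralog sites are identical between the two call sets.
#'
#' @param reference a [make_reference()] result.
#' @param config a [sim_config()].
#' @param truth a [ground_truth()].
#' @return list with `haploid` and `diploid` [callset()]s and
#'   `paralog_sites`, a data frame of the injected collapsed-paralog
#'   positions (`contig`, `pos`).
#' @export
simulate_cohort <- function(reference, config, truth) {
  stopifnot(inherits(reference, "hapsel_reference"),
            inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  ns <- config$n_samples
  dm <- demography(nu = truth$N2_ratio, t2 = truth$t2)
  # neutral expectation sets the background variant density; 0-fold coding
  # positions segregate under the ground-truth gamma DFE instead, which both
  # thins them and skews them towards rare alleles
  e_neutral <- expected_sample_sfs_unfolded(dm, s = 0, n = ns)
  grid <- default_nes_grid()
  w <- gamma_class_weights(truth$beta, truth$Es, grid / dm$ne1)
  e_sel <- w[1] * e_neutral
  for (j in seq_along(grid))
    if (w[j + 1] > 1e-12)
      e_sel <- e_sel + w[j + 1] *
        expected_sample_sfs_unfolded(dm, -grid[j] / dm$ne1, ns)
  p_seg <- config$theta_pop * sum(e_neutral)
  p_seg0 <- config$theta_pop * sum(e_sel)
  if (p_seg > 0.9)
    stop("requested SNP density exceeds what the sequence length can hold")
  degmap <- annotate_degeneracy(reference)
  zero_fold <- degmap[degmap$degeneracy == "0-fold", , drop = FALSE]
  bases <- c("A", "C", "G", "T")
  samples <- sprintf("sample%02d", seq_len(ns))

  with_seed(derive_seed(config$seed, 31), {
    per_gene <- vector("list", config$n_genes)
    paralog_sites <- list()
    for (i in seq_len(config$n_genes)) {
      ctg <- as.character(names(reference$seq)[i])
      seq_i <- strsplit(as.character(reference$seq[[i]]), "")[[1]]
      len <- length(seq_i)
      sel_pos <- zero_fold$pos[zero_fold$contig == ctg]
      p_site <- rep(p_seg, len)
      p_site[sel_pos] <- p_seg0
      is_snp <- runif(len) < p_site
      # collapsed-paralog divergent positions (>= 1 per flagged gene)
      par_pos <- integer(0)
      if (truth$paralog[i]) {
        n_div <- max(1L, rbinom(1, len, config$paralog_divergence))
        par_pos <- sort(sample.int(len, n_div))
        is_snp[par_pos] <- FALSE
      }
      pos <- seq_len(len)
      ref <- seq_i
      alt <- rep(".", len)
      gt_h <- matrix("0", len, ns)
      het <- matrix(FALSE, len, ns)
      for (p in which(is_snp)) {
        alt[p] <- sample(setdiff(bases, ref[p]), 1)
        fw <- if (p %in% sel_pos) e_sel else e_neutral
        k <- sample.int(ns - 1, 1, prob = fw)
        gt_h[p, sample.int(ns, k)] <- "1"
      }
      for (p in par_pos) {
        alt[p] <- sample(setdiff(bases, ref[p]), 1)
        gt_h[p, ] <- as.character(rbinom(ns, 1, 0.5))
        het[p, ] <- TRUE
      }
      miss <- matrix(runif(len * ns) < config$missing_rate, len, ns)
      dp <- matrix(rnbinom(len * ns, mu = config$depth_mean,
                           size = config$depth_size), len, ns)
      gq <- matrix(1 + rpois(len * ns, max(config$gq_mean - 1, 0)), len, ns)
      if (length(par_pos) > 0)
        paralog_sites[[length(paralog_sites) + 1]] <-
          data.frame(contig = ctg, pos = par_pos, stringsAsFactors = FALSE)
      per_gene[[i]] <- list(contig = rep(ctg, len), pos = pos, ref = ref,
                            alt = alt, gt = gt_h, het = het, miss = miss,
                            dp = dp, gq = gq)
    }

    contig <- unlist(lapply(per_gene, `[[`, "contig"))
    pos <- unlist(lapply(per_gene, `[[`, "pos"))
    ref <- unlist(lapply(per_gene, `[[`, "ref"))
    alt <- unlist(lapply(per_gene, `[[`, "alt"))
    gt <- do.call(rbind, lapply(per_gene, `[[`, "gt"))
    het <- do.call(rbind, lapply(per_gene, `[[`, "het"))
    miss <- do.call(rbind, lapply(per_gene, `[[`, "miss"))
    dp <- do.call(rbind, lapply(per_gene, `[[`, "dp"))
    gq <- do.call(rbind, lapply(per_gene, `[[`, "gq"))
    colnames(gt) <- colnames(gq) <- colnames(dp) <- samples

    gt_h <- gt
    gt_h[miss] <- "."
    gq_m <- gq; dp_m <- dp
    gq_m[miss] <- NA_real_; dp_m[miss] <- NA_real_
    haploid <- callset(contig, pos, ref, alt, gt_h, gq_m, dp_m, 1L, samples)

    # diploid-mode call: variant records only, homozygous except paralog sites
    keep <- alt != "."
    gt_d <- matrix(paste(gt, gt, sep = "/"), nrow(gt))
    gt_d[het] <- "0/1"
    gt_d[miss] <- "./."
    gt_d <- gt_d[keep, , drop = FALSE]
    colnames(gt_d) <- samples
    diploid <- callset(contig[keep], pos[keep], ref[keep], alt[keep],
                       gt_d, gq_m[keep, , drop = FALSE],
                       dp_m[keep, , drop = FALSE], 2L, samples)

    ps <- if (length(paralog_sites) > 0) do.call(rbind, paralog_sites)
    else data.frame(contig = character(0), pos = integer(0),
                    stringsAsFactors = FALSE)
    list(haploid = haploid, diploid = diploid, paralog_sites = ps)
  })
}

#' Write the cohort call sets to VCF
#'
#' @param cohort a [simulate_cohort()] result.
#' @param haploid_path,diploid_path output VCF paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, haploid_path, diploid_path) {
  write_vcf(cohort$haploid, haploid_path)
  write_vcf(cohort$diploid, diploid_path)
  invisible(c(haploid = haploid_path, diploid = diploid_path))
}
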