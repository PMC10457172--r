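#' Run the full synthetic-to-comparison pipeline
#'
#' Executes the whole inference chain on a synthetic data set with known
#' ground truth: simulate -> variant QC (paralog mask + filters) ->
#' degeneracy annotation -> tau classification -> diversity -> folded SFS
#' replicates -> DFE fits -> gamma-shape overlap. The run is a pure function
#' of `(config, truth, options)`: rerunning with the same configuration
#' yields byte-identical tables.
#'
#' @param config a [sim_config()]; its `seed` drives every stage.
#' @param truth optional [ground_truth()]; defaults to `ground_truth(config)`.
#' @param tau_min tissue-specificity threshold (default 0.8).
#' @param gq_min,dp_min,max_missing,window_bp variant QC thresholds.
#' @param min_sites combined 0-fold + 4-fold site minimum for the per-gene
#'   diversity ratio (default 50; lower it for very small simulations).
#' @param n_down sample size used for the SFS-based statistics and DFE
#'   (default 16).
#' @param dfe_reps number of SFS resampling replicates fed to the DFE
#'   (default 200, the study-scale convention; reduce for quick runs).
#' @param gene_sets which gene sets to take through the SFS/DFE stages;
#'   default: every tissue set plus `all_genes`.
#' @param outdir optional directory; when given, all tables are written as
#'   TSV plus a JSON run manifest.
#' @return list with elements `site_table`, `tau_table`, `gene_sets`,
#'   `diversity` (per-gene and per-set summary), `summary_table`
#'   (diversity/SFS-statistic table per gene set), `sfs_long`, `dfe`
#'   (per-set replicate fits and class summaries), `beta_overlap` (symmetric
#'   percent matrix), `manifest`, and the simulated inputs.
#' @export
run_pipeline <- function(config, truth = NULL, tau_min = 0.8,
                         gq_min = 20, dp_min = 10, max_missing = 0.20,
                         window_bp = 150, min_sites = 50, n_down = 16,
                         dfe_reps = 200, gene_sets = NULL, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) truth <- ground_truth(config)
  stages <- character(0)
  note <- function(s) stages <<- c(stages, s)

  ## 1. simulate
  reference <- make_reference(config)
  cohort <- simulate_cohort(reference, config, truth)
  expr <- simulate_expression(config, truth)
  note("simulate")

  ## 2. variant QC
  flagged <- detect_paralog_sites(cohort$diploid)
  mask <- build_mask(flagged, window_bp = window_bp)
  qc <- apply_filters(cohort$haploid, mask, gene_map = reference$gene_map,
                      gq_min = gq_min, dp_min = dp_min,
                      max_missing = max_missing)
  note("qc")

  ## 3. degeneracy
  degmap <- annotate_degeneracy(reference)
  sites <- restrict_sites(qc$sites, degmap)
  note("annotate")

  ## 4. expression / tau
  tt <- tau_table(expr)
  sets <- select_tissue_specific(tt, tau_min = tau_min)
  if (!is.null(gene_sets)) sets <- sets[gene_sets]
  note("tau")

  ## 5. diversity
  div <- diversity_by_gene(sites)
  ratios <- pi_ratio_table(div, gene_sets = sets, min_sites = min_sites)
  note("diversity")

  ## 6. folded SFS replicates (+ one fixed draw per set for the summaries)
  sites_fixed <- fix_reference_mismatch(sites)
  usable <- vapply(names(sets), function(nm) {
    sub <- sites_fixed[sites_fixed$gene %in% sets[[nm]] &
                         sites_fixed$an >= n_down, , drop = FALSE]
    sum(sub$degeneracy == "0-fold") > 0 && sum(sub$degeneracy == "4-fold") > 0
  }, logical(1))
  if (any(!usable))
    message("gene set(s) without usable sites skipped: ",
            paste(names(sets)[!usable], collapse = ", "))
  sets <- sets[usable]
  sfs <- list()
  stat_rows <- list()
  for (nm in names(sets)) {
    for (cl in c("0-fold", "4-fold")) {
      sub <- sites_fixed[sites_fixed$degeneracy == cl &
                           sites_fixed$gene %in% sets[[nm]], , drop = FALSE]
      sfs[[nm]][[cl]] <- build_replicates(sub, n_list = n_down,
                                          reps = dfe_reps,
                                          seed = derive_seed(config$seed, 51),
                                          class_label = cl, gene_set = nm)
    }
    f0 <- sfs[[nm]][["0-fold"]][[as.character(n_down)]][[1]]
    f4 <- sfs[[nm]][["4-fold"]][[as.character(n_down)]][[1]]
    gset <- sets[[nm]]
    gidx <- match(gset, names(reference$seq))
    stat_rows[[nm]] <- data.frame(
      gene_set = nm, n_genes_set = length(gset),
      theta_w_0fold = watterson_theta(f0), d_0fold = as.numeric(tajimas_d(f0)),
      d_0fold_undefined = isTRUE(attr(tajimas_d(f0), "undefined")),
      theta_w_4fold = watterson_theta(f4), d_4fold = as.numeric(tajimas_d(f4)),
      d_4fold_undefined = isTRUE(attr(tajimas_d(f4), "undefined")),
      gc_percent = gc_content(reference$seq[gidx[!is.na(gidx)]]),
      stringsAsFactors = FALSE)
  }
  sfs_stats <- do.call(rbind, stat_rows)
  rownames(sfs_stats) <- NULL
  note("sfs")

  ## 7. DFE per gene set
  dfe <- list()
  for (nm in names(sets)) {
    s0 <- sfs[[nm]][["0-fold"]][[as.character(n_down)]]
    s4 <- sfs[[nm]][["4-fold"]][[as.character(n_down)]]
    dfe[[nm]] <- run_replicates(s0, s4, seed = derive_seed(config$seed, 52))
  }
  note("dfe")

  ## 8. beta-distribution overlap between gene sets
  nmv <- names(sets)
  ov <- matrix(NA_real_, length(nmv), length(nmv), dimnames = list(nmv, nmv))
  for (i in seq_along(nmv)) for (j in seq_len(i)) {
    bi <- dfe[[nmv[i]]]$beta
    bj <- dfe[[nmv[j]]]$beta
    ov[i, j] <- ov[j, i] <- if (length(bi) >= 2 && length(bj) >= 2)
      suppressWarnings(kde_overlap(bi, bj)$overlap) else NA_real_
  }
  note("compare")

  ## summary table (diversity + SFS statistics per gene set)
  summary_table <- merge(ratios$summary, sfs_stats, by = "gene_set",
                         sort = TRUE)
  manifest <- list(
    package = "hapsel",
    version = as.character(utils::packageVersion("hapsel")),
    seed = config$seed,
    config_hash = config_hash(config),
    stages_completed = stages,
    n_stages = length(stages),
    truth = list(beta = truth$beta, Es = truth$Es,
                 N2_ratio = truth$N2_ratio, t2 = truth$t2),
    dfe_reps = dfe_reps, n_down = n_down)

  out <- list(reference = reference, cohort = cohort, expression = expr,
              paralog_flagged = flagged, mask = mask, site_table = sites, tau_table = tt,
              gene_sets = sets, diversity = ratios,
              summary_table = summary_table,
              sfs = sfs, sfs_long = do.call(rbind, lapply(
                unlist(sfs, recursive = FALSE), sfs_long)),
              dfe = dfe, beta_overlap = ov, manifest = manifest,
              truth = truth)
  rownames(out$sfs_long) <- NULL
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(config[order(names(unclass(config)))], tmp)
  unname(tools::md5sum(tmp))
}

write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  tsv(out$site_table, "site_table.tsv")
  tsv(out$tau_table, "tau_table.tsv")
  tsv(out$diversity$genes, "diversity_genes.tsv")
  tsv(out$summary_table, "summary_table.tsv")
  tsv(out$sfs_long, "sfs_replicates.tsv")
  fits <- do.call(rbind, lapply(names(out$dfe), function(nm)
    cbind(gene_set = nm, out$dfe[[nm]]$fits)))
  tsv(fits, "dfe_fits.tsv")
  cls <- do.call(rbind, lapply(names(out$dfe), function(nm)
    cbind(gene_set = nm, out$dfe[[nm]]$class_summary)))
  tsv(cls, "dfe_class_proportions.tsv")
  ovdf <- data.frame(gene_set = rownames(out$beta_overlap),
                     out$beta_overlap, check.names = FALSE)
  tsv(ovdf, "beta_overlap.tsv")
  writeLines(jsonlite::toJSON(out$manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(outdir, "manifest.json"))
  invisible(outdir)
}
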