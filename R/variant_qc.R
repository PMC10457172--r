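#' Detect collapsed-paralog sites from a diploid-mode call of haploid samples
#'
#' Samples drawn from haploid tissue cannot be truly heterozygous, so any
#' site where the diploid-mode caller reports two or more heterozygous
#' genotypes is taken as evidence of diverged paralogous copies collapsed
#' onto one reference locus.
#'
#' @param diploid a diploid-mode [callset()].
#' @param min_het minimum number of heterozygous samples for a site to be
#'   flagged (default 2).
#' @return data frame of flagged positions (`contig`, `pos`, `n_het`).
#' @export
detect_paralog_sites <- function(diploid, min_het = 2L) {
  stopifnot(inherits(diploid, "hapsel_callset"))
  if (diploid$ploidy != 2L)
    stop("paralog detection requires a diploid-mode call set")
  n_het <- rowSums(matrix(gt_het(diploid$gt), nrow = n_sites(diploid)))
  keep <- n_het >= min_het
  data.frame(contig = diploid$contig[keep], pos = diploid$pos[keep],
             n_het = as.integer(n_het[keep]), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Build a merged mask around flagged sites
#'
#' Each flagged position is surrounded by a window centred on the site
#' (`floor(window_bp / 2)` bp on each side); overlapping windows are merged.
#' Intervals are 0-based half-open (BED convention).
#'
#' @param flagged data frame with `contig` and `pos` (1-based site positions).
#' @param window_bp window length (default 150, i.e. +/- 75 bp around the
#'   site).
#' @return data frame `contig, start, end` of merged intervals, sorted.
#' @export
#' @examples
#' build_mask(data.frame(contig = "c1", pos = 1000), window_bp = 150)
build_mask <- function(flagged, window_bp = 150L) {
  if (window_bp < 1) stop("window_bp must be >= 1")
  if (nrow(flagged) == 0)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  half <- floor(window_bp / 2)
  out <- lapply(split(flagged$pos, flagged$contig), function(p) {
    ir <- IRanges::reduce(IRanges::IRanges(start = pmax(p - half, 1),
                                           end = p + half))
    data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, Map(function(ct, df) cbind(contig = ct, df),
                            names(out), out))
  rownames(res) <- NULL
  res[order(res$contig, res$start), , drop = FALSE]
}

#' Write a mask as BED
#' @param mask a [build_mask()] result (0-based half-open already).
#' @param path output BED path.
#' @return invisibly, `path`.
#' @export
write_mask_bed <- function(mask, path) {
  write.table(mask, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# TRUE for positions (1-based) falling inside mask intervals
in_mask <- function(contig, pos, mask) {
  hit <- logical(length(pos))
  if (is.null(mask) || nrow(mask) == 0) return(hit)
  for (ct in unique(mask$contig)) {
    m <- mask[mask$contig == ct, , drop = FALSE]
    sel <- contig == ct
    if (!any(sel)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = pos[sel], width = 1L),
      IRanges::IRanges(start = m$start + 1L, end = m$end))
    hit[which(sel)[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  hit
}

#' Apply paralog mask and genotype/site filters to a haploid call
#'
#' Filter order: (1) drop records inside the mask; (2) drop indels, complex
#' variants and sites with more than two alleles; (3) set genotypes with
#' GQ <= `gq_min` or DP <= `dp_min` to missing (strict "greater than"
#' thresholds are required to keep a genotype); (4) drop sites whose missing
#' fraction exceeds `max_missing`; (5) recompute AN and AC from the surviving
#' genotypes.
#'
#' @param haploid a haploid-mode [callset()] with invariant sites.
#' @param mask optional [build_mask()] result.
#' @param gene_map optional site-to-gene map (`contig, start, end, gene`,
#'   0-based half-open); fills the `gene` column of the site table.
#' @param gq_min,dp_min genotype-level thresholds; genotypes are kept only
#'   when GQ > `gq_min` and DP > `dp_min`.
#' @param max_missing maximum tolerated fraction of missing genotypes per
#'   site.
#' @return list with `sites` (data frame `contig, pos, gene, an, ac,
#'   degeneracy`) and `callset` (the filtered haploid call, on which the
#'   function is idempotent).
#' @export
apply_filters <- function(haploid, mask = NULL, gene_map = NULL,
                          gq_min = 20, dp_min = 10, max_missing = 0.20) {
  stopifnot(inherits(haploid, "hapsel_callset"))
  if (haploid$ploidy != 1L)
    stop("apply_filters expects the haploid-mode call")
  bad <- is.na(haploid$ref) | haploid$ref == "" | is.na(haploid$alt)
  if (any(bad))
    stop("malformed records at position(s): ",
         paste(haploid$pos[bad], collapse = ", "))
  x <- haploid

  keep <- !in_mask(x$contig, x$pos, mask)
  snp <- x$ref %in% c("A", "C", "G", "T") &
    (x$alt == "." | x$alt %in% c("A", "C", "G", "T"))
  keep <- keep & snp
  x <- subset_callset(x, keep)

  drop_gt <- is.na(x$gq) | is.na(x$dp) | x$gq <= gq_min | x$dp <= dp_min
  x$gt[drop_gt] <- "."
  x$gq[drop_gt] <- NA_real_
  x$dp[drop_gt] <- NA_real_

  miss_frac <- rowMeans(gt_missing(x$gt))
  x <- subset_callset(x, miss_frac <= max_missing)

  an <- rowSums(!gt_missing(x$gt))
  ac <- rowSums(x$gt == "1")
  gene <- rep(NA_character_, n_sites(x))
  if (!is.null(gene_map) && n_sites(x) > 0) {
    for (r in seq_len(nrow(gene_map))) {
      sel <- x$contig == gene_map$contig[r] &
        x$pos > gene_map$start[r] & x$pos <= gene_map$end[r]
      gene[sel] <- gene_map$gene[r]
    }
  }
  sites <- data.frame(contig = x$contig, pos = x$pos, gene = gene,
                      an = as.integer(an), ac = as.integer(ac),
                      degeneracy = NA_character_, stringsAsFactors = FALSE,
                      row.names = NULL)
  list(sites = sites, callset = x)
}
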