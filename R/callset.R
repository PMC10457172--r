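#' Construct a call set
#'
#' In-memory representation of a (possibly invariant-including) variant call:
#' one row per site, one column per sample, with VCF-style genotype strings
#' plus per-genotype quality (GQ) and depth (DP). Haploid genotypes carry one
#' allele (`"0"`, `"1"`, `"."`), diploid genotypes two (`"0/1"`, `"./."`).
#' Invariant records have `alt == "."`.
#'
#' @param contig,pos,ref,alt per-site vectors; `pos` is 1-based and must be
#'   strictly increasing within each contig.
#' @param gt character matrix (sites x samples) of genotype strings.
#' @param gq,dp numeric matrices (sites x samples); `NA` where missing.
#' @param ploidy 1 or 2.
#' @param samples sample names.
#' @return an object of class `hapsel_callset`.
#' @export
callset <- function(contig, pos, ref, alt, gt, gq, dp, ploidy,
                    samples = colnames(gt)) {
  gt <- as.matrix(gt); gq <- as.matrix(gq); dp <- as.matrix(dp)
  if (is.null(samples)) samples <- sprintf("sample%02d", seq_len(ncol(gt)))
  x <- structure(list(contig = as.character(contig), pos = as.integer(pos),
                      ref = as.character(ref), alt = as.character(alt),
                      gt = gt, gq = gq, dp = dp,
                      ploidy = as.integer(ploidy),
                      samples = as.character(samples)),
                 class = "hapsel_callset")
  validate_callset(x)
}

validate_callset <- function(x) {
  n <- length(x$pos)
  stopifnot(length(x$contig) == n, length(x$ref) == n, length(x$alt) == n,
            nrow(x$gt) == n, nrow(x$gq) == n, nrow(x$dp) == n,
            ncol(x$gt) == length(x$samples), x$ploidy %in% c(1L, 2L))
  for (ct in unique(x$contig)) {
    p <- x$pos[x$contig == ct]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within contig ", ct)
  }
  sep <- grepl("[/|]", x$gt)
  if (x$ploidy == 1L && any(sep))
    stop("haploid call set contains multi-allele genotype strings")
  if (x$ploidy == 2L && any(!sep & x$gt != "."))
    stop("diploid call set contains single-allele genotype strings")
  x
}

#' @export
print.hapsel_callset <- function(x, ...) {
  cat(sprintf("call set: ploidy %d, %d sites (%d variant) x %d samples\n",
              x$ploidy, length(x$pos), sum(x$alt != "."), length(x$samples)))
  invisible(x)
}

n_sites <- function(x) length(x$pos)

# TRUE where the genotype string is missing
gt_missing <- function(gt) gt == "." | gt == "./." | gt == ".|."

# TRUE where a diploid genotype carries two distinct called alleles
gt_het <- function(gt) {
  a <- sub("^([0-9.]+)[/|]([0-9.]+)$", "\\1", gt)
  b <- sub("^([0-9.]+)[/|]([0-9.]+)$", "\\2", gt)
  ok <- grepl("[/|]", gt) & a != "." & b != "."
  ok & a != b
}

subset_callset <- function(x, keep) {
  callset(x$contig[keep], x$pos[keep], x$ref[keep], x$alt[keep],
          x$gt[keep, , drop = FALSE], x$gq[keep, , drop = FALSE],
          x$dp[keep, , drop = FALSE], x$ploidy, x$samples)
}

#' Write a call set as VCF v4.2
#'
#' Emits GT:GQ:DP genotypes; invariant records carry `ALT = "."`. The header
#' is fully deterministic (no timestamps), so identical call sets produce
#' byte-identical files.
#'
#' @param x a [callset()].
#' @param path output file (plain text).
#' @return invisibly, `path`.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "hapsel_callset"))
  ctg <- unique(x$contig)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=hapsel",
           sprintf("##contig=<ID=%s>", ctg),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$samples), collapse = "\t"))
  gqc <- ifelse(is.na(x$gq), ".", format(x$gq, trim = TRUE, scientific = FALSE))
  dpc <- ifelse(is.na(x$dp), ".", format(x$dp, trim = TRUE, scientific = FALSE))
  cells <- matrix(paste(x$gt, gqc, dpc, sep = ":"), nrow = n_sites(x))
  body <- paste(x$contig, x$pos, ".", x$ref, x$alt, ".", ".", ".", "GT:GQ:DP",
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a call set
#'
#' Thin wrapper around [vcfR::read.vcfR()] that extracts GT, GQ and DP and
#' infers the ploidy from the genotype strings. Both variant and invariant
#' (`ALT = "."`) records are kept.
#'
#' @param path VCF file (plain or gzipped).
#' @return a [callset()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, "GT", convertNA = FALSE)
  gq <- suppressWarnings(vcfR::extract.gt(v, "GQ", as.numeric = TRUE))
  dp <- suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE))
  gt[is.na(gt)] <- "."
  ploidy <- if (any(grepl("[/|]", gt))) 2L else 1L
  if (ploidy == 2L) gt[gt == "."] <- "./."
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- "."
  callset(fix[, "CHROM"], as.integer(fix[, "POS"]), fix[, "REF"], alt,
          gt, gq, dp, ploidy, colnames(gt))
}
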