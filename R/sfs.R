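#' Folded site frequency spectrum container
#'
#' Counts of sites over minor-allele-count bins `0..floor(n/2)` at a fixed
#' downsampled size `n`. Bin 0 holds sites that are invariant in the
#' subsample (including sites made invariant by the AN = AC reference fix or
#' by the downsampling itself).
#'
#' @param n sample size (number of alleles).
#' @param bins counts over bins `0..floor(n/2)`.
#' @param class_label optional degeneracy class ("0-fold"/"4-fold").
#' @param gene_set optional gene-set label.
#' @param replicate optional replicate id.
#' @param seed optional seed used to draw the replicate.
#' @return object of class `folded_sfs`.
#' @export
folded_sfs <- function(n, bins, class_label = NA_character_,
                       gene_set = NA_character_, replicate = NA_integer_,
                       seed = NA_integer_) {
  n <- as.integer(n)
  if (n < 2) stop("n must be >= 2")
  if (length(bins) != floor(n / 2) + 1)
    stop("bins must cover minor-allele counts 0..floor(n/2)")
  if (any(bins < 0)) stop("negative bin counts")
  structure(list(n = n, bins = setNames(as.numeric(bins),
                                        0:floor(n / 2)),
                 class_label = class_label, gene_set = gene_set,
                 replicate = as.integer(replicate), seed = seed),
            class = "folded_sfs")
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat(sprintf("folded SFS, n = %d (%s%s): %d sites, %d segregating\n",
              x$n, ifelse(is.na(x$gene_set), "-", x$gene_set),
              ifelse(is.na(x$class_label), "", paste0("/", x$class_label)),
              sum(x$bins), sum(x$bins[-1])))
  print(x$bins)
  invisible(x)
}

#' Reset the alternate count of alternate-monomorphic sites
#'
#' Sites where every non-missing call carries the alternate allele
#' (`AN == AC`) are monomorphic within the cohort and only differ from the
#' reference assembly; their AC is set to 0 so they enter the invariant bin.
#'
#' @param sites a site table.
#' @return the site table with `ac` zeroed where `an == ac > 0`.
#' @export
fix_reference_mismatch <- function(sites) {
  sites$ac[sites$an == sites$ac & sites$an > 0] <- 0L
  sites
}

#' Downsample one site to n alleles without replacement
#'
#' Draws the alternate count of a hypergeometric subsample of `n` of the
#' `AN` called alleles and folds it to the minor-allele count. Sites with
#' fewer than `n` called alleles are dropped (`NA`).
#'
#' @param an,ac allele number and alternate count of the site.
#' @param n target number of alleles (>= 2).
#' @return folded minor-allele count in `0..floor(n/2)`, or `NA` when
#'   `an < n`.
#' @export
downsample_site <- function(an, ac, n) {
  if (n < 2) stop("n must be >= 2")
  if (ac > an) stop("AC exceeds AN")
  if (an < n) return(NA_integer_)
  k <- rhyper(1, m = ac, n = an - ac, k = n)
  as.integer(min(k, n - k))
}

#' Build one folded SFS by downsampling a site table
#'
#' Every site with `AN >= n` is independently downsampled without
#' replacement to `n` alleles and the folded counts are tabulated.
#' [fix_reference_mismatch()] should be applied first.
#'
#' @param sites site table (one degeneracy class / gene set).
#' @param n target allele count.
#' @param seed optional seed for the draw.
#' @param class_label,gene_set,replicate labels stored in the result.
#' @return a [folded_sfs()].
#' @export
build_sfs <- function(sites, n, seed = NULL, class_label = NA_character_,
                      gene_set = NA_character_, replicate = NA_integer_) {
  keep <- sites$an >= n
  an <- sites$an[keep]
  ac <- sites$ac[keep]
  draw <- function() {
    k <- rep(0L, length(an))
    poly <- ac > 0
    if (any(poly))
      k[poly] <- rhyper(sum(poly), m = ac[poly], n = an[poly] - ac[poly], k = n)
    folded <- pmin(k, n - k)
    tabulate(folded + 1L, nbins = floor(n / 2) + 1L)
  }
  bins <- if (is.null(seed)) draw() else with_seed(seed, draw())
  folded_sfs(n, bins, class_label, gene_set, replicate,
             if (is.null(seed)) NA_integer_ else seed)
}

#' Replicate downsampled folded SFSs over several sample sizes
#'
#' For each target size `n` and each replicate, every retained site is
#' independently re-downsampled; replicate seeds are derived from the master
#' seed, so the whole collection is reproducible. With 20 haploid samples,
#' sizes 16 to 20 correspond to tolerating from 20\% down to 0\% missing
#' genotypes per site.
#'
#' @param sites site table (apply [fix_reference_mismatch()] first).
#' @param n_list target allele counts (default `16:20`).
#' @param reps replicates per size (default 200).
#' @param seed master seed.
#' @param class_label,gene_set labels stored in the results.
#' @return nested list: `result[[as.character(n)]][[rep]]` is a
#'   [folded_sfs()].
#' @export
build_replicates <- function(sites, n_list = 16:20, reps = 200, seed = 1,
                             class_label = NA_character_,
                             gene_set = NA_character_) {
  out <- lapply(n_list, function(n) {
    lapply(seq_len(reps), function(r) {
      build_sfs(sites, n, seed = derive_seed(seed, n * 100003 + r),
                class_label = class_label, gene_set = gene_set,
                replicate = r)
    })
  })
  names(out) <- as.character(n_list)
  out
}

#' Long-format table of a replicate SFS collection
#' @param repset result of [build_replicates()].
#' @return data frame `gene_set, class, n, replicate, bin, count`.
#' @export
sfs_long <- function(repset) {
  rows <- list()
  for (n in names(repset)) for (f in repset[[n]]) {
    rows[[length(rows) + 1]] <- data.frame(
      gene_set = f$gene_set, class = f$class_label, n = f$n,
      replicate = f$replicate, bin = as.integer(names(f$bins)),
      count = as.numeric(f$bins), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a folded SFS in the two-line text exchange format
#'
#' Line 1 holds the sample size `n`; line 2 holds `n + 1` counts (folded
#' bins `0..floor(n/2)` padded with zeros above), the layout used by
#' SFS-based DFE tools.
#'
#' @param fsfs a [folded_sfs()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fsfs <- function(fsfs, path) {
  padded <- c(fsfs$bins, rep(0, fsfs$n + 1 - length(fsfs$bins)))
  writeLines(c(as.character(fsfs$n),
               paste(format(padded, trim = TRUE, scientific = FALSE),
                     collapse = " ")), path)
  invisible(path)
}

#' @rdname write_fsfs
#' @export
read_fsfs <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  vals <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
  if (length(vals) != n + 1) stop("malformed SFS file")
  folded_sfs(n, vals[seq_len(floor(n / 2) + 1)])
}
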