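#' Nucleotide diversity from allele counts, invariant sites included
#'
#' Ratio-of-sums estimator: `pi = sum_s AC_s (AN_s - AC_s) / sum_s C(AN_s, 2)`
#' over variant and invariant sites. Sites with fewer than two non-missing
#' alleles contribute no comparisons and per-site values are never
#' renormalised, so missing data reduce the weight of a site rather than
#' biasing the estimate.
#'
#' @param an non-missing allele numbers per site.
#' @param ac alternate allele counts per site.
#' @return pi per site; `NA` when no site offers a comparable pair.
#' @export
#' @examples
#' pi_nucleotide(an = rep(4, 10), ac = c(2, rep(0, 9)))  # 4/60
pi_nucleotide <- function(an, ac) {
  stopifnot(length(an) == length(ac))
  if (any(ac > an)) stop("AC exceeds AN")
  pairs <- sum(choose(an, 2))
  if (pairs == 0) return(NA_real_)
  sum(ac * (an - ac)) / pairs
}

#' Per-gene diversity at 0-fold and 4-fold sites
#'
#' @param sites site table with `gene`, `an`, `ac` and a filled `degeneracy`
#'   column (see [restrict_sites()]).
#' @return data frame `gene, pi0, pi4, n_sites_0, n_sites_4` where site
#'   counts tally sites with at least two non-missing alleles.
#' @export
diversity_by_gene <- function(sites) {
  stopifnot(all(c("gene", "an", "ac", "degeneracy") %in% names(sites)))
  genes <- sort(unique(sites$gene[!is.na(sites$gene)]))
  one <- function(g, cl) {
    s <- sites[!is.na(sites$gene) & sites$gene == g &
                 sites$degeneracy == cl & sites$an >= 2, , drop = FALSE]
    c(pi = if (nrow(s) == 0) NA_real_ else pi_nucleotide(s$an, s$ac),
      n = nrow(s))
  }
  res0 <- vapply(genes, one, numeric(2), cl = "0-fold")
  res4 <- vapply(genes, one, numeric(2), cl = "4-fold")
  data.frame(gene = genes, pi0 = res0["pi", ], pi4 = res4["pi", ],
             n_sites_0 = as.integer(res0["n", ]),
             n_sites_4 = as.integer(res4["n", ]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-gene pi0/pi4 ratios with the length and positivity filters
#'
#' Keeps genes with both estimates available and a combined 0-fold + 4-fold
#' site count of at least `min_sites`; the ratio is reported only where both
#' diversities are positive. When gene sets are supplied, per-set means and
#' standard errors (sample SD / sqrt(N genes), mean of per-gene ratios) are
#' summarised.
#'
#' @param div output of [diversity_by_gene()].
#' @param gene_sets optional named list of gene-id vectors.
#' @param min_sites minimum combined number of sites (default 50).
#' @return list with `genes` (per-gene table with `ratio`) and `summary`
#'   (per-set means with SEs; `NULL` when `gene_sets` is missing).
#' @export
pi_ratio_table <- function(div, gene_sets = NULL, min_sites = 50) {
  g <- div[!is.na(div$pi0) & !is.na(div$pi4) &
             (div$n_sites_0 + div$n_sites_4) >= min_sites, , drop = FALSE]
  g$ratio <- ifelse(g$pi0 > 0 & g$pi4 > 0, g$pi0 / g$pi4, NA_real_)
  summary <- NULL
  if (!is.null(gene_sets)) {
    summary <- do.call(rbind, lapply(names(gene_sets), function(nm) {
      s <- g[g$gene %in% gene_sets[[nm]], , drop = FALSE]
      r <- s$ratio[!is.na(s$ratio)]
      data.frame(gene_set = nm, n_genes = nrow(s),
                 pi0_mean = mean(s$pi0), pi0_se = se_mean(s$pi0),
                 pi4_mean = mean(s$pi4), pi4_se = se_mean(s$pi4),
                 n_ratio = length(r),
                 ratio_mean = if (length(r)) mean(r) else NA_real_,
                 ratio_se = se_mean(r), stringsAsFactors = FALSE)
    }))
    rownames(summary) <- NULL
  }
  list(genes = g, summary = summary)
}

se_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x) / sqrt(length(x))
}

#' Watterson's theta per site from a folded SFS
#'
#' `theta_W = S / (a1 * L)` with `S` the number of segregating sites,
#' `a1 = sum_{i=1}^{n-1} 1/i` and `L` the total number of sites (bin 0
#' included).
#'
#' @param fsfs a [folded_sfs()].
#' @return theta per site (0 when nothing segregates).
#' @export
watterson_theta <- function(fsfs) {
  stopifnot(inherits(fsfs, "folded_sfs"))
  S <- sum(fsfs$bins[-1])
  L <- sum(fsfs$bins)
  if (L == 0) stop("empty SFS")
  a1 <- sum(1 / seq_len(fsfs$n - 1))
  S / (a1 * L)
}

#' Tajima's D from a folded SFS
#'
#' Standard variance normalisation (beta-shaped weights in `n`): pairwise
#' diversity is accumulated as `sum_i eta_i i (n - i) / C(n, 2)` over folded
#' bins, which is exact because a site with minor count `i` contributes
#' `i (n - i)` pairwise differences whichever allele is minor. With no
#' segregating sites the statistic is undefined and is reported as 0 with
#' attribute `undefined = TRUE` so summary tables can still be laid out.
#'
#' @param fsfs a [folded_sfs()].
#' @return Tajima's D (attribute `undefined` flags the S = 0 case).
#' @export
tajimas_d <- function(fsfs) {
  stopifnot(inherits(fsfs, "folded_sfs"))
  n <- fsfs$n
  eta <- fsfs$bins[-1]
  i <- seq_along(eta)
  S <- sum(eta)
  if (S == 0) return(structure(0, undefined = TRUE))
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  pi_tot <- sum(eta * i * (n - i)) / choose(n, 2)
  d <- (pi_tot - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  structure(d, undefined = FALSE)
}
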