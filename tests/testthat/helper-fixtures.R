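# shared fixture builders; everything is generated in code at test time

small_config <- function(seed = 1, n_genes = 20, ...) {
  sim_config(n_samples = 20, n_genes = n_genes, gene_length = 150,
             flank = 30, seed = seed, ...)
}

# haploid call set with hand-placed boundary cases for the filter tests:
# 20 samples, one contig
toy_haploid_callset <- function() {
  ns <- 20
  pos <- c(100L, 200L, 300L, 400L, 500L, 600L, 700L, 800L, 900L, 1000L)
  ref <- c("A", "A", "G", "T", "C", "A", "AT", "C", "G", "T")
  alt <- c(".", "C", "A", "G", "T", "C,T", "A", "TG", "A", "A")
  gt <- matrix("0", length(pos), ns)
  gq <- matrix(60, length(pos), ns)
  dp <- matrix(30, length(pos), ns)
  gt[2, 1:5] <- "1"                      # clean SNP, AC = 5
  gt[3, 1] <- "1"; gt[3, 2:3] <- "1"     # carrier 1 will be GQ-masked
  gq[3, 1] <- 20                         # GQ = 20 exactly -> masked (strict >)
  gt[4, 1:3] <- "1"
  dp[4, 2] <- 10                         # DP = 10 exactly -> masked (strict >)
  gq[5, 1:5] <- 10                       # 5/20 masked = 25% missing -> dropped
  gt[6, 1:2] <- "1"                      # triallelic -> dropped
  gt[9, 1:4] <- "1"                      # will sit inside the mask
  gt[10, 5:8] <- "1"                     # AC = 4 among the called genotypes
  gt[10, 1:4] <- "."                     # 4/20 = 20% missing exactly -> kept
  gq[10, 1:4] <- NA; dp[10, 1:4] <- NA
  callset(rep("c1", length(pos)), pos, ref, alt, gt, gq, dp, 1L)
}

# diploid call set for paralog detection: het in {3,7} at pos 50, het in {3}
# only at pos 60, all-homozygous at pos 70
toy_diploid_callset <- function() {
  ns <- 10
  pos <- c(50L, 60L, 70L)
  gt <- matrix("0/0", length(pos), ns)
  gt[1, c(3, 7)] <- "0/1"
  gt[2, 3] <- "0/1"
  callset(rep("c1", length(pos)), pos, rep("A", 3), rep("G", 3),
          gt, matrix(60, 3, ns), matrix(30, 3, ns), 2L)
}

# site table builders
site_row <- function(pos, an, ac, gene = "g1", cl = "4-fold", contig = "c1") {
  data.frame(contig = contig, pos = pos, gene = gene, an = an, ac = ac,
             degeneracy = cl, stringsAsFactors = FALSE)
}

# exhaustive pairwise-difference oracle for pi on a 0/1 haplotype matrix
# (sites x samples, NA = missing); independent of pi_nucleotide()
pi_pairwise_oracle <- function(hap) {
  ns <- ncol(hap)
  diffs <- 0
  pairs <- 0
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    ok <- !is.na(hap[, i]) & !is.na(hap[, j])
    diffs <- diffs + sum(hap[ok, i] != hap[ok, j])
    pairs <- pairs + sum(ok)
  }
  if (pairs == 0) return(NA_real_)
  diffs / pairs
}

hap_to_sites <- function(hap) {
  data.frame(contig = "c1", pos = seq_len(nrow(hap)), gene = "g1",
             an = rowSums(!is.na(hap)), ac = rowSums(hap == 1, na.rm = TRUE),
             degeneracy = "4-fold", stringsAsFactors = FALSE)
}

# independent degeneracy oracle: substitute every base at every position and
# translate with seqinr (a different code path than the implementation)
degeneracy_oracle <- function(cds) {
  ch <- strsplit(cds, "")[[1]]
  n <- length(ch)
  aa_of <- function(chars) {
    paste(seqinr::translate(tolower(chars)), collapse = "")
  }
  cls <- character(n)
  for (i in seq_len(n)) {
    cstart <- 3 * ((i - 1) %/% 3) + 1
    codon <- ch[cstart:(cstart + 2)]
    aa0 <- aa_of(codon)
    nsyn <- 0
    for (b in setdiff(c("A", "C", "G", "T"), ch[i])) {
      mut <- codon
      mut[i - cstart + 1] <- b
      if (aa_of(mut) == aa0) nsyn <- nsyn + 1
    }
    cls[i] <- c("0-fold", "2-fold", "3-fold", "4-fold")[nsyn + 1]
  }
  cls
}

random_cds <- function(n_codons, seed) {
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- names(Biostrings::GENETIC_CODE)
  withr::with_seed(seed, {
    paste(c("ATG", sample(setdiff(all_codons, stops), n_codons - 2,
                          replace = TRUE), sample(stops, 1)), collapse = "")
  })
}
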