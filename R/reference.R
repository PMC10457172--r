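#' Generate a synthetic reference with gene models
#'
#' Builds one contig per gene: a random non-coding flank, a CDS (starting ATG,
#' free of internal stop codons, ending in a stop codon), and a second flank.
#' A configurable fraction of genes is placed on the minus strand, in which
#' case the contig carries the reverse complement of the coding sequence.
#'
#' @param config a [sim_config()].
#' @return an object of class `hapsel_reference`: a list with
#'   \describe{
#'     \item{seq}{[Biostrings::DNAStringSet] of contigs (one per gene)}
#'     \item{genes}{gene models: `contig, start, end, strand, gene, phase`
#'       (1-based inclusive coordinates)}
#'     \item{gene_map}{site-to-gene map: `contig, start, end, gene`
#'       (0-based half-open, BED-style) covering each whole contig}
#'   }
#' @export
#' @examples
#' ref <- make_reference(sim_config(n_genes = 2, seed = 3))
#' ref$genes
make_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  if (config$n_genes < 1) stop("n_genes must be >= 1")
  g <- config$n_genes
  len <- config$gene_length
  fl <- config$flank
  stops <- c("TAA", "TAG", "TGA")
  codons <- setdiff(names(Biostrings::GENETIC_CODE), stops)
  with_seed(derive_seed(config$seed, 21), {
    n_minus <- round(config$minus_strand_fraction * g)
    strand <- sample(c(rep("-", n_minus), rep("+", g - n_minus)))
    seqs <- character(g)
    for (i in seq_len(g)) {
      cds <- paste0("ATG",
                    paste(sample(codons, len / 3 - 2, replace = TRUE),
                          collapse = ""),
                    sample(stops, 1))
      if (strand[i] == "-")
        cds <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(cds)))
      seqs[i] <- paste0(random_dna(fl), cds, random_dna(fl))
    }
    ids <- gene_ids(g)
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- ids
    genes <- data.frame(contig = ids, start = fl + 1L, end = fl + len,
                        strand = strand, gene = ids, phase = 0L,
                        stringsAsFactors = FALSE)
    gene_map <- data.frame(contig = ids, start = 0L, end = 2L * fl + len,
                           gene = ids, stringsAsFactors = FALSE)
    structure(list(seq = dna, genes = genes, gene_map = gene_map),
              class = "hapsel_reference")
  })
}

random_dna <- function(n) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Write a synthetic reference to FASTA and GFF3
#'
#' @param reference a [make_reference()] result.
#' @param fasta,gff output paths.
#' @return invisibly, the two paths.
#' @export
write_reference <- function(reference, fasta, gff) {
  stopifnot(inherits(reference, "hapsel_reference"))
  Biostrings::writeXStringSet(reference$seq, fasta)
  gm <- reference$genes
  lines <- c("##gff-version 3",
             sprintf("%s\thapsel\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds-%s;Parent=%s",
                     gm$contig, gm$start, gm$end, gm$strand, gm$phase,
                     gm$gene, gm$gene))
  writeLines(lines, gff)
  invisible(c(fasta = fasta, gff = gff))
}

#' Read gene models from a GFF3 file
#'
#' Keeps CDS features and returns them in the column layout used throughout
#' the package (1-based inclusive coordinates).
#'
#' @param path GFF3 file.
#' @return data frame `contig, start, end, strand, gene, phase`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  gene <- if (!is.null(gr$Parent) && any(lengths(gr$Parent) > 0))
    vapply(as.list(gr$Parent), function(p) p[1], character(1))
  else as.character(gr$ID)
  ph <- if (is.null(gr$phase)) 0L else as.integer(as.character(gr$phase))
  ph[is.na(ph)] <- 0L
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)), gene = gene,
             phase = ph, stringsAsFactors = FALSE, row.names = NULL)
}
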