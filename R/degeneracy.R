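#' Classify coding positions by codon degeneracy
#'
#' A CDS position is 4-fold degenerate when all three possible nucleotide
#' substitutions leave the amino acid unchanged and 0-fold when none does
#' (one and two synonymous substitutions give 2-fold and 3-fold). Degeneracy
#' is evaluated per position from the standard genetic code, which handles
#' the irregular codon families (e.g. isoleucine, the serine split) without
#' a family lookup table. Minus-strand genes are evaluated on the reverse
#' complement. Positions covered by overlapping CDS annotations that disagree
#' on the class are dropped.
#'
#' @param reference a [make_reference()] result, a
#'   [Biostrings::DNAStringSet], or a named character vector of contig
#'   sequences.
#' @param genes gene models (`contig, start, end, strand, gene, phase`,
#'   1-based inclusive); defaults to the models carried by `reference`.
#' @return data frame `contig, pos, gene, degeneracy` with one row per
#'   classified CDS position; `degeneracy` is one of `"0-fold"`, `"2-fold"`,
#'   `"3-fold"`, `"4-fold"`.
#' @export
annotate_degeneracy <- function(reference, genes = NULL) {
  if (inherits(reference, "hapsel_reference")) {
    if (is.null(genes)) genes <- reference$genes
    seqs <- reference$seq
  } else if (is.character(reference)) {
    seqs <- Biostrings::DNAStringSet(reference)
  } else seqs <- reference
  if (is.null(genes)) stop("gene models are required")

  out <- list()
  for (id in unique(genes$gene)) {
    frag <- genes[genes$gene == id, , drop = FALSE]
    minus <- frag$strand[1] == "-"
    frag <- frag[order(frag$start, decreasing = minus), , drop = FALSE]
    cds_chars <- character(0)
    gpos <- integer(0)
    for (r in seq_len(nrow(frag))) {
      s <- as.character(Biostrings::subseq(seqs[[frag$contig[r]]],
                                           frag$start[r], frag$end[r]))
      if (minus)
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      ch <- strsplit(s, "")[[1]]
      gp <- if (minus) seq(frag$end[r], frag$start[r]) else
        seq(frag$start[r], frag$end[r])
      if (r == 1 && frag$phase[1] > 0) {       # trim leading out-of-frame bases
        ch <- ch[-seq_len(frag$phase[1])]
        gp <- gp[-seq_len(frag$phase[1])]
      }
      cds_chars <- c(cds_chars, ch)
      gpos <- c(gpos, gp)
    }
    L <- length(cds_chars)
    if (L %% 3 != 0) {
      warning("gene ", id, ": CDS length not a multiple of 3, skipped")
      next
    }
    cls <- codon_degeneracy(cds_chars)
    if (is.null(cls)) {
      warning("gene ", id, ": internal stop codon, skipped")
      next
    }
    out[[id]] <- data.frame(contig = rep(frag$contig[1], L), pos = gpos,
                            gene = id, degeneracy = cls,
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(contig = character(0), pos = integer(0),
                      gene = character(0), degeneracy = character(0),
                      stringsAsFactors = FALSE))
  map <- do.call(rbind, out)
  rownames(map) <- NULL
  # overlapping CDS with conflicting classes: drop the position
  key <- paste(map$contig, map$pos)
  n_classes <- tapply(map$degeneracy, key, function(z) length(unique(z)))
  conflicted <- names(n_classes)[n_classes > 1]
  map <- map[!(key %in% conflicted), , drop = FALSE]
  map[!duplicated(paste(map$contig, map$pos)), , drop = FALSE]
}

# per-position class vector for a CDS given as a character vector;
# NULL if an internal stop codon is present
codon_degeneracy <- function(ch) {
  code <- Biostrings::GENETIC_CODE
  n_codon <- length(ch) / 3
  codons <- paste0(ch[seq(1, length(ch), 3)], ch[seq(2, length(ch), 3)],
                   ch[seq(3, length(ch), 3)])
  if (any(!codons %in% names(code))) return(NULL)   # ambiguity codes
  aa <- unname(code[codons])
  if (any(aa[-n_codon] == "*")) return(NULL)
  bases <- c("A", "C", "G", "T")
  cls <- character(length(ch))
  for (w in 1:3) {
    idx <- seq(w, length(ch), 3)
    orig <- ch[idx]
    nsyn <- integer(n_codon)
    for (b in bases) {
      mut <- codons
      substr(mut, w, w) <- b
      nsyn <- nsyn + as.integer(unname(code[mut]) == aa & orig != b)
    }
    cls[idx] <- c("0-fold", "2-fold", "3-fold", "4-fold")[nsyn + 1L]
  }
  cls
}

#' Keep only sites at selected degeneracy classes
#'
#' Joins a site table with a degeneracy map and retains sites whose position
#' falls in one of the requested classes, filling the `degeneracy` column.
#'
#' @param sites site table from [apply_filters()].
#' @param map degeneracy map from [annotate_degeneracy()].
#' @param classes classes to keep (default 0-fold and 4-fold).
#' @return the filtered site table with `degeneracy` filled.
#' @export
restrict_sites <- function(sites, map, classes = c("0-fold", "4-fold")) {
  map <- map[map$degeneracy %in% classes, , drop = FALSE]
  i <- match(paste(sites$contig, sites$pos), paste(map$contig, map$pos))
  keep <- !is.na(i)
  out <- sites[keep, , drop = FALSE]
  out$degeneracy <- map$degeneracy[i[keep]]
  rownames(out) <- NULL
  out
}

#' GC content of a sequence set, in percent
#'
#' `100 * (G + C) / (A + C + G + T)`; ambiguity codes are excluded from the
#' denominator.
#'
#' @param seqs a [Biostrings::DNAStringSet] or character vector.
#' @return a single percentage.
#' @export
#' @examples
#' gc_content(c("ATGC", "GGCC"))
gc_content <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (length(seqs) == 0) stop("empty sequence set")
  counts <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
  tot <- sum(counts)
  if (tot == 0) stop("no unambiguous bases in input")
  100 * sum(counts[, c("C", "G")]) / tot
}
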