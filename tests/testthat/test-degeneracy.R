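test_that("textbook codon classes are recovered", {
  # GGG (glycine): third position 4-fold, first/second 0-fold
  ref <- Biostrings::DNAStringSet(c(c1 = "ATGGGGTAA"))
  genes <- data.frame(contig = "c1", start = 1L, end = 9L, strand = "+",
                      gene = "g1", phase = 0L)
  map <- annotate_degeneracy(ref, genes)
  expect_equal(map$degeneracy[map$pos %in% 1:3], rep("0-fold", 3))  # ATG
  expect_equal(map$degeneracy[map$pos == 6], "4-fold")              # GGg
  expect_equal(map$degeneracy[map$pos %in% 4:5], rep("0-fold", 2))
})

test_that("minus-strand genes classify as their plus-strand reverse complement", {
  for (seed in c(1, 2, 3)) {
    cds <- random_cds(30, seed)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    plus <- annotate_degeneracy(
      Biostrings::DNAStringSet(c(cp = cds)),
      data.frame(contig = "cp", start = 1L, end = nchar(cds), strand = "+",
                 gene = "g", phase = 0L))
    minus <- annotate_degeneracy(
      Biostrings::DNAStringSet(c(cm = rc)),
      data.frame(contig = "cm", start = 1L, end = nchar(cds), strand = "-",
                 gene = "g", phase = 0L))
    # CDS coordinate i on the plus contig maps to end - i + 1 on the minus one
    expect_identical(minus$degeneracy[match(nchar(cds) - plus$pos + 1,
                                            minus$pos)],
                     plus$degeneracy)
  }
})

test_that("classes match a brute-force all-substitutions translator", {
  skip_if_not_installed("seqinr")
  for (seed in 1:100) {
    cds <- random_cds(8, seed)
    got <- annotate_degeneracy(
      Biostrings::DNAStringSet(c(c1 = cds)),
      data.frame(contig = "c1", start = 1L, end = nchar(cds), strand = "+",
                 gene = "g", phase = 0L))
    expect_identical(got$degeneracy[order(got$pos)], degeneracy_oracle(cds))
  }
})

test_that("class counts tile the CDS and invalid genes are skipped", {
  ref <- make_reference(small_config(seed = 17))
  map <- annotate_degeneracy(ref)
  counts <- table(map$gene)
  expect_true(all(counts == ref$genes$end - ref$genes$start + 1))
  # length not a multiple of 3
  expect_warning(
    annotate_degeneracy(Biostrings::DNAStringSet(c(cx = "ATGCC")),
                        data.frame(contig = "cx", start = 1L, end = 5L,
                                   strand = "+", gene = "g", phase = 0L)),
    "multiple of 3")
  # internal stop
  expect_warning(
    annotate_degeneracy(Biostrings::DNAStringSet(c(cx = "ATGTAAGGGTAA")),
                        data.frame(contig = "cx", start = 1L, end = 12L,
                                   strand = "+", gene = "g", phase = 0L)),
    "stop")
})

test_that("conflicting overlapping CDS positions are dropped", {
  # two genes share contig positions but disagree on the class
  ref <- Biostrings::DNAStringSet(c(c1 = "ATGGGGGGGTAAATG"))
  genes <- data.frame(contig = "c1", start = c(1L, 4L), end = c(9L, 12L),
                      strand = "+", gene = c("g1", "g2"), phase = 0L)
  map <- annotate_degeneracy(ref, genes)
  key <- paste(map$contig, map$pos)
  expect_false(any(duplicated(key)))
})

test_that("restrict_sites equals a brute-force intersection", {
  ref <- make_reference(small_config(seed = 23))
  map <- annotate_degeneracy(ref)
  st <- data.frame(contig = sample(ref$genes$contig, 200, replace = TRUE),
                   pos = sample.int(210, 200, replace = TRUE),
                   gene = NA_character_, an = 20L, ac = 1L,
                   degeneracy = NA_character_, stringsAsFactors = FALSE)
  st <- st[!duplicated(paste(st$contig, st$pos)), ]
  out <- restrict_sites(st, map)
  key_m <- paste(map$contig, map$pos)[map$degeneracy %in% c("0-fold", "4-fold")]
  expect_setequal(paste(out$contig, out$pos),
                  intersect(paste(st$contig, st$pos), key_m))
  expect_true(all(out$degeneracy %in% c("0-fold", "4-fold")))
  # 2-fold-only map: empty intersection
  map2 <- map[map$degeneracy == "2-fold", ]
  expect_equal(nrow(restrict_sites(st, map2)), 0)
})

test_that("gc content follows its definition", {
  expect_equal(gc_content("GCGC"), 100)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content(c("AT", "GCGC")), 100 * 4 / 6)
  expect_equal(gc_content("ATNNGC"), 50)      # ambiguity codes excluded
  expect_error(gc_content("NNNN"), "unambiguous")
})
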