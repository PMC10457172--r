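test_that("reference generation is deterministic and respects strand mix", {
  cfg <- small_config(seed = 42, minus_strand_fraction = 0.5)
  ref1 <- make_reference(cfg)
  ref2 <- make_reference(cfg)
  expect_identical(as.character(ref1$seq), as.character(ref2$seq))
  expect_identical(ref1$genes, ref2$genes)
  # even gene count: strand fractions match the request exactly
  expect_equal(sum(ref1$genes$strand == "-"), cfg$n_genes / 2)
  # byte-identical FASTA on re-write
  f1 <- tempfile(); f2 <- tempfile()
  write_reference(ref1, f1, tempfile())
  write_reference(ref2, f2, tempfile())
  expect_identical(readLines(f1), readLines(f2))
})

test_that("every CDS starts with ATG and has no internal stop", {
  ref <- make_reference(small_config(seed = 7))
  for (i in seq_len(nrow(ref$genes))) {
    g <- ref$genes[i, ]
    s <- Biostrings::subseq(ref$seq[[g$contig]], g$start, g$end)
    if (g$strand == "-") s <- Biostrings::reverseComplement(s)
    aa <- as.character(Biostrings::translate(s))
    expect_identical(substr(aa, 1, 1), "M")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
  expect_error(make_reference(sim_config(n_genes = 0)), "n_genes")
})

test_that("gene models written to GFF3 round-trip through the reader", {
  ref <- make_reference(small_config(seed = 3))
  gff <- tempfile(fileext = ".gff3")
  write_reference(ref, tempfile(fileext = ".fa"), gff)
  back <- read_gene_models(gff)
  expect_equal(back$start, ref$genes$start)
  expect_equal(back$end, ref$genes$end)
  expect_equal(back$strand, ref$genes$strand)
})

test_that("cohort simulation honours the paralog flag", {
  cfg0 <- small_config(seed = 5, paralog_fraction = 0)
  co0 <- simulate_cohort(make_reference(cfg0), cfg0, ground_truth(cfg0))
  expect_equal(nrow(co0$paralog_sites), 0)
  expect_false(any(hapsel:::gt_het(co0$diploid$gt)))

  cfg1 <- small_config(seed = 5, paralog_fraction = 1,
                       paralog_divergence = 0.02)
  co1 <- simulate_cohort(make_reference(cfg1), cfg1, ground_truth(cfg1))
  # every gene carries at least one site with >= 2 heterozygous diploid calls
  flagged <- detect_paralog_sites(co1$diploid)
  expect_setequal(unique(flagged$contig), unique(co1$diploid$contig))
})

test_that("diploid and haploid calls agree at non-paralog sites", {
  cfg <- small_config(seed = 9, paralog_fraction = 0.3)
  co <- simulate_cohort(make_reference(cfg), cfg, ground_truth(cfg))
  key_d <- paste(co$diploid$contig, co$diploid$pos)
  key_p <- paste(co$paralog_sites$contig, co$paralog_sites$pos)
  idx_h <- match(key_d, paste(co$haploid$contig, co$haploid$pos))
  for (r in which(!key_d %in% key_p)) {
    hd <- co$diploid$gt[r, ]
    hh <- co$haploid$gt[idx_h[r], ]
    ok <- hh != "."
    expect_identical(unname(hd[ok]), paste(hh[ok], hh[ok], sep = "/"))
    expect_identical(unname(hd[!ok]), rep("./.", sum(!ok)))
  }
})

test_that("missingness matches its binomial expectation", {
  cfg <- sim_config(n_samples = 20, n_genes = 4, gene_length = 300,
                    flank = 0, missing_rate = 0.2, seed = 8)
  co <- simulate_cohort(make_reference(cfg), cfg, ground_truth(cfg))
  n_gt <- length(co$haploid$gt)
  expect_gte(n_gt, 10000 * 2)
  obs <- mean(co$haploid$gt == ".")
  sd3 <- 3 * sqrt(0.2 * 0.8 / n_gt)
  expect_lt(abs(obs - 0.2), sd3)
})

test_that("cohort VCFs round-trip through the reader without loss", {
  cfg <- small_config(seed = 12, n_genes = 5)
  co <- simulate_cohort(make_reference(cfg), cfg, ground_truth(cfg))
  hv <- tempfile(fileext = ".vcf"); dv <- tempfile(fileext = ".vcf")
  write_cohort(co, hv, dv)
  h2 <- read_vcf(hv); d2 <- read_vcf(dv)
  for (fld in c("contig", "pos", "ref", "alt", "ploidy"))
    expect_equal(h2[[fld]], co$haploid[[fld]])
  expect_equal(unname(h2$gt), unname(co$haploid$gt))
  expect_equal(unname(h2$gq), unname(co$haploid$gq))
  expect_equal(unname(h2$dp), unname(co$haploid$dp))
  expect_equal(unname(d2$gt), unname(co$diploid$gt))
})

test_that("simulated expression hits the target tau and spans both regimes", {
  cfg <- sim_config(n_genes = 50, seed = 21)
  tr <- ground_truth(cfg)
  mat <- simulate_expression(cfg, tr)
  recovered <- apply(mat, 1, tau)
  expect_lt(max(abs(recovered - tr$tau)), 0.01)
  expect_gt(sum(tr$tau >= 0.8), 0)
  expect_gt(sum(tr$tau < 0.8), 0)
  # determinism
  expect_identical(mat, simulate_expression(cfg, tr))
  # invalid targets rejected
  tr_bad <- tr; tr_bad$tau[1] <- 1.2
  expect_error(simulate_expression(cfg, tr_bad), "outside")
})

test_that("fsfs pair simulation is deterministic and checks inputs", {
  tr <- ground_truth(small_config(seed = 2))
  a <- simulate_fsfs_pair(tr, 1e4, 1e4, 16, seed = 4)
  b <- simulate_fsfs_pair(tr, 1e4, 1e4, 16, seed = 4)
  expect_identical(a$fsfs0$bins, b$fsfs0$bins)
  expect_identical(a$fsfs4$bins, b$fsfs4$bins)
  expect_error(simulate_fsfs_pair(tr, 0, 1e4, 16), "L0")
  expect_equal(sum(a$fsfs4$bins), sum(rpois(0, 0)) + sum(a$fsfs4$bins))
  expect_equal(length(a$fsfs4$bins), 9)
})

test_that("neutral fsfs draws scatter around the folded coalescent shape", {
  tr <- ground_truth(small_config(seed = 2))   # equilibrium truth
  tot <- 0
  reps <- 40
  for (r in seq_len(reps))
    tot <- tot + simulate_fsfs_pair(tr, 1e3, 2e5, 16, seed = r)$fsfs4$bins[-1]
  n <- 16
  neutral <- vapply(1:8, function(i) (1 / i + 1 / (n - i)) / (1 + (i == 8)),
                    numeric(1))
  expected <- sum(tot) * neutral / sum(neutral)
  # 4 sigma Poisson tolerance per bin on the replicate-summed counts
  expect_true(all(abs(tot - expected) < 4 * sqrt(expected) + 4))
})
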