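test_that("paralog detection needs two or more heterozygous calls", {
  d <- toy_diploid_callset()
  fl <- detect_paralog_sites(d)
  expect_equal(fl$pos, 50L)          # het in samples {3, 7}
  expect_equal(fl$n_het, 2L)         # single-het site at 60 not flagged
  # all-homozygous call set
  d2 <- d; d2$gt[] <- "0/0"
  expect_equal(nrow(detect_paralog_sites(d2)), 0)
  # haploid input rejected
  expect_error(detect_paralog_sites(toy_haploid_callset()), "diploid")
  # missing genotypes never count as heterozygous
  d3 <- d; d3$gt[2, ] <- "./."
  expect_equal(detect_paralog_sites(d3)$pos, 50L)
})

test_that("mask windows are centred and merged", {
  m <- build_mask(data.frame(contig = "c1", pos = 1000L), window_bp = 150)
  expect_equal(m$start, 924L)
  expect_equal(m$end, 1075L)
  # two sites 10 bp apart merge into one interval
  m2 <- build_mask(data.frame(contig = "c1", pos = c(1000L, 1010L)))
  expect_equal(nrow(m2), 1)
  expect_equal(c(m2$start, m2$end), c(924L, 1085L))
  # empty input, and window validation
  expect_equal(nrow(build_mask(data.frame(contig = character(0),
                                          pos = integer(0)))), 0)
  expect_error(build_mask(data.frame(contig = "c1", pos = 5L),
                          window_bp = 0), "window_bp")
})

test_that("genotype and site filters follow the strict thresholds", {
  x <- toy_haploid_callset()
  mask <- build_mask(data.frame(contig = "c1", pos = 900L))
  res <- apply_filters(x, mask)
  st <- res$sites
  # survivors: invariant 100, clean SNP 200, boundary-masked 300/400, 20% 1000
  expect_equal(st$pos, c(100L, 200L, 300L, 400L, 1000L))
  expect_equal(st$an, c(20L, 20L, 19L, 19L, 16L))
  expect_equal(st$ac, c(0L, 5L, 2L, 2L, 4L))
  # GQ = 20 genotype was set missing (strict ">"), dropping one alt allele
  expect_identical(res$callset$gt[res$callset$pos == 300, 1][[1]], ".")
})

test_that("filtering is idempotent and AN/AC match a brute-force recount", {
  cfg <- small_config(seed = 14, paralog_fraction = 0.2)
  co <- simulate_cohort(make_reference(cfg), cfg, ground_truth(cfg))
  mask <- build_mask(detect_paralog_sites(co$diploid))
  r1 <- apply_filters(co$haploid, mask)
  r2 <- apply_filters(r1$callset, mask)
  expect_equal(r2$sites, r1$sites)
  # brute-force oracle from the raw call set
  key <- paste(co$haploid$contig, co$haploid$pos)
  idx <- match(paste(r1$sites$contig, r1$sites$pos), key)
  for (k in seq_along(idx)) {
    i <- idx[k]
    kept <- co$haploid$gt[i, ] != "." &
      !is.na(co$haploid$gq[i, ]) & co$haploid$gq[i, ] > 20 &
      !is.na(co$haploid$dp[i, ]) & co$haploid$dp[i, ] > 10
    expect_equal(r1$sites$an[k], sum(kept))
    expect_equal(r1$sites$ac[k], sum(co$haploid$gt[i, kept] == "1"))
  }
})

test_that("paralog recovery on synthetic cohorts is exact", {
  cfg <- small_config(seed = 31, paralog_fraction = 0.5,
                      missing_rate = 0.05)
  co <- simulate_cohort(make_reference(cfg), cfg, ground_truth(cfg))
  flagged <- detect_paralog_sites(co$diploid)
  # every injected site with >= 2 non-missing samples must be flagged, and
  # nothing else can be heterozygous in this simulation
  key_f <- paste(flagged$contig, flagged$pos)
  key_p <- paste(co$paralog_sites$contig, co$paralog_sites$pos)
  idx <- match(key_p, paste(co$diploid$contig, co$diploid$pos))
  n_called <- rowSums(co$diploid$gt[idx, , drop = FALSE] != "./.")
  expect_setequal(key_f, key_p[n_called >= 2])
  # paralog-free cohort: no flags at all
  cfg0 <- small_config(seed = 31, paralog_fraction = 0)
  co0 <- simulate_cohort(make_reference(cfg0), cfg0, ground_truth(cfg0))
  expect_equal(nrow(detect_paralog_sites(co0$diploid)), 0)
})

test_that("masking removes exactly the windowed positions", {
  x <- toy_haploid_callset()
  mask <- build_mask(data.frame(contig = "c1", pos = c(200L, 900L)))
  res <- apply_filters(x, mask)
  inside <- x$pos > mask$start[1] & x$pos <= mask$end[1] |
    x$pos > mask$start[2] & x$pos <= mask$end[2]
  expect_true(!any(res$sites$pos %in% x$pos[inside]))
})
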