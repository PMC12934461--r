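test_that("flag pairs map to template strands per the stranded convention", {
  expect_equal(assign_template_strand(99L, 147L), "+")
  expect_equal(assign_template_strand(147L, 99L), "+")
  expect_equal(assign_template_strand(83L, 163L), "-")
  expect_equal(assign_template_strand(163L, 83L), "-")
  expect_equal(assign_template_strand(4L, 8L), "unassigned")
  expect_equal(assign_template_strand(c(99L, 83L, 0L), c(147L, 163L, 16L)),
               c("+", "-", "unassigned"))
})

test_that("read_fragments parses CIGAR deletions and drops secondaries", {
  sam <- c("@HD\tVN:1.6\tSO:coordinate",
           "@SQ\tSN:chr1\tLN:10000",
           "r1\t99\tchr1\t101\t60\t70M9D80M\t=\t110\t168\t*\t*",
           "r1\t147\tchr1\t110\t60\t150M\t=\t101\t-168\t*\t*",
           "r2\t355\tchr1\t500\t60\t150M\t=\t600\t250\t*\t*",
           "r2\t403\tchr1\t600\t60\t150M\t=\t500\t-250\t*\t*")
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, path)
  rec <- read_fragments(path)
  expect_equal(nrow(rec), 1L)           # secondary pair excluded
  g <- rec$gap_blocks[[1]]
  expect_equal(nrow(g), 1L)
  expect_equal(g[1, 2] - g[1, 1], 9)
  expect_equal(g[1, 1], 100 + 70)       # 0-based: pos 101 + 70M
  expect_equal(rec$start, 100)
  expect_equal(rec$template_strand, "+")
})

test_that("fragment filtering matches a brute-force oracle", {
  rec <- random_records(500, seed = 21)
  rec$duplicate[1:5] <- TRUE
  rec <- rbind(rec, rec[10:20, ])       # coordinate duplicates
  bl <- genomic_sites(chrom = "chr1", start = c(1000L, 30000L),
                      end = c(1200L, 31000L), site_class = "other")
  out <- filter_fragments(rec, blacklist = bl, mode = "chip")
  # oracle: per-fragment loop, blacklist then keep-first dedup
  keep <- logical(nrow(rec))
  seen <- character()
  for (i in seq_len(nrow(rec))) {
    hit <- any(rec$start[i] < bl$end & rec$end[i] > bl$start)
    k <- paste(rec$chrom[i], rec$start[i], rec$end[i],
               rec$template_strand[i])
    keep[i] <- !hit && !rec$duplicate[i] && !(k %in% seen)
    if (!hit && !rec$duplicate[i]) seen <- c(seen, k)
  }
  expect_equal(out$start, rec$start[keep])
  expect_equal(out$end, rec$end[keep])
  tally <- attr(out, "tally")
  expect_equal(unname(tally["input"] - tally["blacklist"] -
                        tally["duplicate"]), nrow(out))
})

test_that("blacklist overlap uses the 1-bp boundary rule", {
  rec <- random_records(1, seed = 1)
  rec$start <- 100L; rec$end <- 400L
  bl_touch <- genomic_sites("chr1", 399L, 500L, site_class = "other")
  bl_miss <- genomic_sites("chr1", 400L, 500L, site_class = "other")
  expect_equal(nrow(filter_fragments(rec, bl_touch)), 0L)
  expect_equal(nrow(filter_fragments(rec, bl_miss)), 1L)
})

test_that("atac mode additionally removes improper pairs and chrM", {
  rec <- random_records(100, seed = 22)
  rec$chrom[1:10] <- "chrM"
  chip <- filter_fragments(rec, mode = "chip")
  atac <- filter_fragments(rec, mode = "atac")
  expect_true(any(!chip$proper_pair))   # chip retains improper pairs
  expect_false(any(!atac$proper_pair))
  expect_false(any(atac$chrom == "chrM"))
  expect_true(any(chip$chrom == "chrM"))
})

test_that("a single fragment spreads unit coverage over its bins", {
  rec <- random_records(1, seed = 2)
  rec$start <- 100L; rec$end <- 400L
  rec$template_strand <- "+"
  tr <- compute_coverage(rec, bin_size = 50L, chrom_length = 1000L)
  expect_equal(tr$values_plus[3:8], rep(1, 6))
  expect_equal(sum(tr$values_plus), 6)
  expect_equal(sum(tr$values_minus), 0)
})

test_that("strand coverage partitions exactly and conserves fragment bp", {
  for (seed in c(31, 32)) {
    rec <- random_records(2000, seed = seed)
    tr <- compute_coverage(rec, bin_size = 50L, chrom_length = 50000L)
    both <- compute_coverage(
      within(rec, template_strand <- "+"), bin_size = 50L,
      chrom_length = 50000L)
    expect_equal(tr$values_plus + tr$values_minus, both$values_plus)
    expect_equal(sum(tr$values_plus + tr$values_minus) * 50,
                 sum(rec$end - rec$start))
  }
})

test_that("TMM factors: identity, depth recovery, order equivariance", {
  set.seed(41)
  a <- rpois(2000, 10)
  expect_equal(unname(tmm_scale_factors(rbind(s1 = a, s2 = a))), c(1, 1),
               tolerance = 1e-12)
  f <- tmm_scale_factors(rbind(s1 = a, s2 = 2L * a))
  expect_equal(max(abs(a * f["s1"] - 2 * a * f["s2"])), 0)
  b <- rpois(2000, 8); c3 <- rpois(2000, 12)
  f3 <- tmm_scale_factors(rbind(s1 = a, s2 = b, s3 = c3))
  fp <- tmm_scale_factors(rbind(s3 = c3, s1 = a, s2 = b))
  expect_equal(f3[c("s3", "s1", "s2")], fp)
  expect_error(tmm_scale_factors(rbind(s1 = a, bad = 0 * a)), "bad")
})

test_that("skew is the plus-minus difference with a bounded normalized form", {
  tr <- structure(list(chrom = "chr1", bin_size = 50L,
                       values_plus = c(3, 0), values_minus = c(1, 2),
                       scale_factor = 1, n_fragments_used = 6L,
                       chrom_length = 100L),
                  class = "stranded_track")
  sk <- skew_track(tr)
  expect_equal(sk$skew, c(2, -2))
  expect_equal(sk$skew_norm, c(2 / 5, -2 / 3))
  tr$values_minus <- tr$values_plus
  expect_true(all(skew_track(tr)$skew == 0))
})

test_that("track algebra: replicate mean, subtraction, pooling identity", {
  rec1 <- random_records(1000, seed = 51)
  rec2 <- random_records(1000, seed = 52)
  t1 <- compute_coverage(rec1, 50L, 50000L)
  t2 <- compute_coverage(rec2, 50L, 50000L)
  m <- combine_tracks(list(t1, t1), "mean")
  expect_equal(m$values_plus, t1$values_plus)
  s <- combine_tracks(list(t1, t1), "subtract")
  expect_true(all(s$values_plus == 0) && all(s$values_minus == 0))
  # pooling: coverage is additive, so the replicate mean is half the pool
  pooled <- compute_coverage(rbind(rec1, rec2), 50L, 50000L)
  mm <- combine_tracks(list(t1, t2), "mean")
  expect_equal(2 * mm$values_plus, pooled$values_plus)
  expect_equal(2 * mm$values_minus, pooled$values_minus)
  t3 <- compute_coverage(rec1, 100L, 50000L)
  expect_error(combine_tracks(list(t1, t3), "mean"), "mismatch")
})

test_that("rescaling a track rescales values and factor together", {
  rec <- random_records(200, seed = 61)
  tr <- compute_coverage(rec, 50L, 50000L, scale_factor = 2)
  tr2 <- rescale_track(tr, 4)
  expect_equal(tr2$values_plus, 2 * tr$values_plus)
  expect_equal(tr2$scale_factor, 4)
})
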