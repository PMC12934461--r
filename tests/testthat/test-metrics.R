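make_track <- function(values_plus, values_minus = values_plus,
                       bin_size = 50L) {
  structure(list(chrom = "chr1", bin_size = bin_size,
                 values_plus = values_plus, values_minus = values_minus,
                 scale_factor = 1, n_fragments_used = 0L,
                 chrom_length = length(values_plus) * bin_size),
            class = "stranded_track")
}

test_that("metaprofile slices, flips and averages site windows", {
  v <- seq_len(40)                       # 2000 bp track, bin 50
  tr <- make_track(v, 0 * v)
  site <- genomic_sites("chr1", 995L, 1005L, cut = 1000L,
                        site_class = "DSB")
  mp <- metaprofile(tr, site, window = 1000L, signal = "plus")
  expect_equal(unname(mp$profile), v[1:40])          # full-extent slice
  expect_equal(mp$positions, ((1:40) - 20.5) * 50)
  # a flipped site reads the opposite strand, reversed
  site_m <- genomic_sites("chr1", 995L, 1005L, cut = 1000L,
                          orientation = "-", site_class = "DSB")
  mp_m <- metaprofile(tr, site_m, window = 1000L, signal = "plus")
  expect_equal(unname(mp_m$profile), rep(0, 40))     # minus strand is empty
  mp_m2 <- metaprofile(tr, site_m, window = 1000L, signal = "minus")
  expect_equal(unname(mp_m2$profile), rev(v))
  # skew flips with negation
  sk <- skew_track(make_track(v, 0 * v))
  mp_sk <- metaprofile(sk, site_m, window = 1000L)
  expect_equal(unname(mp_sk$profile), -rev(v))
  # all-zero track gives an all-zero profile
  z <- metaprofile(make_track(rep(0, 40)), site, window = 1000L)
  expect_true(all(z$profile == 0))
  # off-track windows are dropped with a message
  expect_message(
    out <- metaprofile(tr, rbind(site, genomic_sites(
      "chr1", 1L, 11L, cut = 5L, site_class = "DSB")), window = 1000L),
    "dropped")
  expect_equal(nrow(out$matrix), 1L)
})

test_that("narrow footprints give narrower metaprofiles than broad ones", {
  fwhm <- function(sigma) {
    ex <- sim_experiment(seed = 71, n_fragments = 40000L,
                         cut_efficiency = 1, resected_fraction = 0,
                         rejoined_fraction = 1, footprint_sigma = sigma)
    tr <- compute_coverage(ex$records, 50L, ex$cfg$genome_length)
    mp <- metaprofile(tr, ex$dsb, window = 5000L, signal = "both")
    prof <- mp$profile - min(mp$profile)
    sum(prof >= max(prof) / 2) * 50
  }
  expect_lt(fwhm(150), fwhm(1000))
})

test_that("span/end classification matches a brute-force oracle", {
  ex <- sim_experiment(seed = 72, n_fragments = 1000L,
                       rejoined_fraction = 0.3)
  site <- ex$dsb[2, ]
  tol <- 5L
  sc <- span_fraction(ex$records, site, tolerance = tol)
  cut <- site$cut
  n_end <- 0L; n_span <- 0L; n_other <- 0L
  for (i in seq_len(nrow(ex$records))) {
    s <- ex$records$start[i]; e <- ex$records$end[i]
    ending <- (s >= cut - tol && s <= cut + tol) ||
      (e >= cut - tol && e <= cut + tol)
    spanning <- !ending && s <= cut - tol && e >= cut + tol
    other <- !ending && !spanning && s <= cut + tol && e >= cut - tol
    n_end <- n_end + ending; n_span <- n_span + spanning
    n_other <- n_other + other
  }
  expect_equal(sc$n_ending, n_end)
  expect_equal(sc$n_spanning, n_span)
  expect_equal(sc$n_other, n_other)
  expect_equal(sc$fraction_ending, n_end / (n_end + n_span))
})

test_that("junction deletions are detected at the configured length", {
  # forced fixture: one fragment with a 9-bp gap at the cut
  rec <- random_records(1, seed = 73)
  rec$start <- 900L; rec$end <- 1109L
  rec$gap_blocks <- list(matrix(c(1000, 1009), 1))
  site <- genomic_sites("chr1", 995L, 1005L, cut = 1000L, site_class = "DSB")
  h <- detect_deletions(rec, site)
  expect_equal(h, data.frame(length = 9L, count = 1L))
  rec$gap_blocks <- list(matrix(numeric(), 0, 2))
  expect_equal(nrow(detect_deletions(rec, site)), 0L)
  # simulator ground truth: modal detected length equals the preset
  ex <- sim_experiment(seed = 74, n_fragments = 10000L,
                       rejoined_fraction = 0.3, deletion_length = 9L)
  hist1 <- detect_deletions(ex$records, ex$dsb[1, ])
  expect_equal(hist1$length[which.max(hist1$count)], 9L)
})

test_that("adjacent-site compilation matches an exhaustive distance filter", {
  set.seed(75)
  dsb <- genomic_sites(chrom = "chr1",
                       start = c(100000L, 300000L) - 4L,
                       end = c(100000L, 300000L) + 4L,
                       cut = c(100000L, 300000L),
                       label = c("d1", "d2"), site_class = "DSB")
  centers <- sort(sample.int(400000L, 200L))
  open <- genomic_sites(chrom = "chr1", start = centers - 300L,
                        end = centers + 300L,
                        label = sprintf("o%d", seq_along(centers)),
                        site_class = "open_chromatin")
  adj <- adjacent_open_sites(dsb, open)
  # oracle: exhaustive per-site filter
  keep <- vapply(seq_len(nrow(open)), function(i) {
    ctr <- (open$start[i] + open$end[i]) %/% 2
    d <- min(abs(ctr - dsb$cut))
    zone <- any(open$start[i] < dsb$cut + 1500 & open$end[i] > dsb$cut - 1500)
    d > 1500 && d < 50000 && !zone
  }, TRUE)
  expect_equal(adj$label, open$label[keep])
  expect_true(all(adj$site_class == "adjacent_open"))
  # boundary rule: 10 kb in, 1 kb and 60 kb out
  probe <- genomic_sites("chr1", c(109700L, 100700L, 159700L),
                         c(110300L, 101300L, 160300L),
                         label = c("in10k", "in1k", "out60k"),
                         site_class = "open_chromatin")
  got <- adjacent_open_sites(dsb[1, ], probe)
  expect_equal(got$label, "in10k")
  # invariance to input order and DSB duplication
  perm <- sample(nrow(open))
  adj2 <- adjacent_open_sites(rbind(dsb, dsb), open[perm, ])
  expect_equal(adj2[, c("chrom", "start", "end", "label")],
               adj[, c("chrom", "start", "end", "label")])
})

test_that("site signal matrices are linear in scale and track values", {
  v <- rep(3, 100)
  tr <- make_track(v)                    # both-strand signal 6 everywhere
  sites <- genomic_sites("chr1", 600L + (1:10) * 300L,
                         610L + (1:10) * 300L, site_class = "DSB")
  ssm <- site_signal_matrix(list(a = tr, b = tr), sites, window = 500L)
  expect_true(all(ssm$values == 6))
  # a site whose window leaves the track yields NA, not an error
  edge <- rbind(sites, genomic_sites("chr1", 1L, 11L, cut = 5L,
                                     site_class = "DSB"))
  ssm_e <- site_signal_matrix(list(a = tr), edge, window = 500L)
  expect_true(is.na(ssm_e$values[11, "a"]))
  expect_true(all(ssm_e$values[1:10, "a"] == 6))
  tr2 <- rescale_track(tr, 2)
  ssm2 <- site_signal_matrix(list(a = tr, b = tr2), sites, window = 500L)
  expect_equal(ssm2$values[, "b"], 2 * ssm2$values[, "a"])
})

test_that("Spearman correlation classes follow the rank structure", {
  set.seed(76)
  x <- rnorm(50)
  m <- cbind(a = x, b = exp(2 * x) + 5,   # strictly monotone transform
             c = -x, d = x + rnorm(50, 0, 2))
  out <- correlate_sites(m)
  expect_equal(out$rho["a", "a"], 1)
  expect_equal(out$rho["a", "b"], 1)      # rank invariance
  expect_equal(out$class["a", "b"], "strong")
  expect_equal(out$rho["a", "c"], -1)
  expect_equal(out$class["a", "c"], "weak")
  expect_true(out$class["a", "d"] %in% c("strong", "moderate", "weak"))
  mz <- cbind(a = x, z = rep(1, 50))
  outz <- correlate_sites(mz)
  expect_true(is.na(outz$rho["a", "z"]))
  expect_equal(outz$class["a", "z"], "undefined")
  expect_error(correlate_sites(m[1:5, ]), ">= 10 sites")
})

test_that("site signals are concordant across replicate simulations", {
  pk <- demo_config(1)$simulation$open_peaks
  sig <- sapply(c(81, 82), function(s) {
    ex <- sim_experiment(seed = s, n_fragments = 60000L, open_peaks = pk)
    tr <- compute_coverage(ex$records, 50L, ex$cfg$genome_length)
    ssm <- site_signal_matrix(list(x = tr), ex$sites, window = 2500L)
    ssm$values[, 1]
  })
  expect_gte(cor(sig[, 1], sig[, 2], method = "spearman"), 0.9)
})

test_that("fold changes recover the configured DSB induction", {
  # conditions isolating the induction parameter: cuts rejoin scarlessly
  # (no truncation dip) and no single-stranded occupancy term
  F <- 10; sig <- 1000; w <- 1000L
  sim_cond <- function(seed, q) {
    ex <- sim_experiment(seed = seed, n_fragments = 60000L,
                         cut_efficiency = q, resected_fraction = 0,
                         rejoined_fraction = 1, dsb_induction_fold = F,
                         footprint_sigma = sig, ssdna_affinity = 0)
    ex
  }
  ctrl <- sim_cond(91, 0)
  trt <- sim_cond(92, 1)
  cm <- count_matrix(list(ctrl = ctrl$records, dsb = trt$records),
                     bin_size = 2000L, chrom_length = 100000L)
  sf <- tmm_scale_factors(cm)
  tracks <- list(
    ctrl = compute_coverage(ctrl$records, 50L, 100000L,
                            scale_factor = sf[["ctrl"]]),
    dsb = compute_coverage(trt$records, 50L, 100000L,
                           scale_factor = sf[["dsb"]]))
  ssm <- site_signal_matrix(tracks, ctrl$dsb, window = w)
  fc <- fold_change(ssm, "ctrl", "dsb", pseudocount = 0)
  # analytic oracle: mean of background + (F-1)-peak Gaussian over the
  # +/- w window around the cut
  expected <- 1 + (F - 1) * sqrt(2 * pi) * sig *
    (stats::pnorm(w / sig) - stats::pnorm(-w / sig)) / (2 * w)
  expect_lt(abs(fc$median_fold - expected) / expected, 0.15)
  expect_lt(abs(fc$median_fold - F) / F, 0.3)
  # arithmetic contract
  m <- matrix(c(0, 9), 1, 2, dimnames = list("s", c("a", "b")))
  expect_equal(fold_change(rbind(m, m)[1:2, ], "a", "b", 1)$folds[[1]], 10)
  expect_equal(fold_change(ssm, "ctrl", "ctrl")$median_fold, 1)
  expect_error(fold_change(ssm, "ctrl", "dsb", -1), "non-negative")
})
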