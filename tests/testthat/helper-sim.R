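# Shared fixtures built in code.

# Random reference with a given seed, as a named character vector.
random_ref <- function(len, seed, name = "chr1") {
  set.seed(seed)
  stats::setNames(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                        collapse = ""), name)
}

# A small simulated experiment: genome + fragments + in-memory records.
sim_experiment <- function(seed, n_fragments = 20000L, ...) {
  cfg <- simulation_config(seed = seed, n_fragments = n_fragments, ...)
  gen <- simulate_genome(cfg)
  fr <- simulate_fragments(cfg, gen$genome, gen$sites)
  rec <- fragments_to_records(fr, cfg)
  list(cfg = cfg, genome = gen$genome, sites = gen$sites,
       dsb = gen$sites[gen$sites$site_class == "DSB", , drop = FALSE],
       fragments = fr, records = rec)
}

# Random fragment_records table (single chromosome), for property tests.
random_records <- function(n, seed, chrom_length = 50000L, chrom = "chr1") {
  set.seed(seed)
  start <- sample.int(chrom_length - 700L, n, replace = TRUE) - 1L
  len <- sample(200:600, n, replace = TRUE)
  out <- data.frame(chrom = chrom, start = start, end = start + len,
                    flag1 = 99L, flag2 = 147L,
                    template_strand = sample(c("+", "-"), n, replace = TRUE),
                    proper_pair = sample(c(TRUE, TRUE, TRUE, FALSE), n,
                                         replace = TRUE),
                    duplicate = FALSE,
                    stringsAsFactors = FALSE)
  out$flag1[out$template_strand == "-"] <- 83L
  out$flag2[out$template_strand == "-"] <- 163L
  out$gap_blocks <- replicate(n, matrix(numeric(), 0, 2), simplify = FALSE)
  class(out) <- c("fragment_records", "data.frame")
  out
}
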