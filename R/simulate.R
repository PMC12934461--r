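# Synthetic stranded paired-end fragment simulator.
#
# Generative model, per sequenced molecule (one fragment = one molecule):
#   1. Each configured DSB site on the molecule is cut with probability q
#      (cut_efficiency). A cut is rejoined with probability rejoined_fraction
#      (end-joining complete, double-stranded again, optionally carrying a
#      junction deletion); an unrejoined cut is resected with probability r
#      (resected_fraction). Resection proceeds 5'->3' independently on each
#      side; the resected span per end is 1 + Geometric(1/L) bases (mean L),
#      leaving the 3'-terminated strand single-stranded: the + strand on the
#      left of the cut, the - strand on the right.
#   2. A binding position x is drawn from an occupancy mixture (densities in
#      multiples of the uniform background, 1 per bp):
#        background                 1 everywhere
#        open-chromatin peak k      Gaussian(center_k, width_k/2) with peak
#                                   density preload_weight * occupancy_k,
#                                   multiplied by adjacent_induction_fold
#                                   when the peak's anchoring DSB (nearest
#                                   cut at 1.5-50 kb) is cut on this molecule
#        cut site j (if cut)        Gaussian(cut_j, footprint_sigma) with
#                                   peak density (dsb_induction_fold - 1), so
#                                   total density at the cut is
#                                   dsb_induction_fold * background
#        resected span              flat ssdna_affinity per bp over the span
#   3. The fragment takes a uniform length in fragment_len_range and a
#      uniform offset covering x, then is truncated at any open (unrejoined)
#      break on its molecule: sheared fragments never cross an open DSB.
#   4. A fragment wholly inside a resected span carries that span's retained
#      template strand; a fragment crossing a rejoined junction is "rejoined"
#      and carries the configured deletion as an alignment gap; everything
#      else is double-stranded ("both").

#' Build a simulation configuration
#'
#' Defaults reflect the assayed system: 200-600 bp sheared fragments read
#' with 150-bp paired-end chemistry, DSB induction raising local signal
#' ~25-fold over background, ~10-fold preloading at open chromatin, and
#' geometric resection with mean length 1500 bp.
#'
#' @param seed integer RNG seed (mandatory; every stochastic stage derives
#'   its stream from it).
#' @param genome_length length of each chromosome (bp).
#' @param n_chroms number of chromosomes; DSBs and open peaks are placed on
#'   the first, the rest contribute undamaged background.
#' @param dsb_sites 0-based motif start coordinates on chromosome 1 where an
#'   AsiSI-style recognition site is planted (cut = start + 4).
#' @param cut_efficiency probability a molecule is cut at assay time (q).
#' @param resected_fraction probability an unrejoined cut is resected (r).
#' @param resection_mean mean resected length per end, bp (L; geometric).
#' @param rejoined_fraction probability a cut has been rejoined by
#'   end-joining at assay time.
#' @param deletion_length bp deleted at the repair junction of rejoined
#'   molecules (0 = scarless).
#' @param open_peaks data.frame(center, width, occupancy) of pre-existing
#'   open-chromatin peaks on chromosome 1 (may have zero rows).
#' @param footprint_sigma Gaussian footprint sd at cuts, bp. 1000 bp models a
#'   broad clamp-like factor; 150 bp a narrow nuclease-like one.
#' @param preload_weight peak occupancy density at open chromatin relative to
#'   background, before damage.
#' @param dsb_induction_fold total-over-background occupancy at a cut.
#' @param adjacent_induction_fold multiplier applied to DSB-adjacent open
#'   peaks (anchoring cut at 1.5-50 kb) when that cut is made.
#' @param ssdna_affinity occupancy density on resected single-stranded spans
#'   relative to background.
#' @param fragment_len_range uniform shear-size range, bp.
#' @param read_length sequenced read length, bp.
#' @param n_fragments number of fragments (molecules) to simulate.
#' @param qpcr list(distances, baseline_ct, noise_sd, n_replicates) for the
#'   restriction-protection qPCR simulator.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              genome_length = 100000L,
                              n_chroms = 1L,
                              dsb_sites = c(20000L, 50000L, 80000L),
                              cut_efficiency = 0.8,
                              resected_fraction = 1,
                              resection_mean = 1500,
                              rejoined_fraction = 0.2,
                              deletion_length = 0L,
                              open_peaks = data.frame(center = numeric(),
                                                      width = numeric(),
                                                      occupancy = numeric()),
                              footprint_sigma = 1000,
                              preload_weight = 10,
                              dsb_induction_fold = 25,
                              adjacent_induction_fold = 3,
                              ssdna_affinity = 5,
                              fragment_len_range = c(200L, 600L),
                              read_length = 150L,
                              n_fragments = 50000L,
                              qpcr = list()) {
  if (missing(seed)) stop("simulation_config: seed is mandatory")
  qpcr_defaults <- list(distances = c(335, 1618, 3500),
                        baseline_ct = 26, noise_sd = 0.1, n_replicates = 3L)
  unknown <- setdiff(names(qpcr), names(qpcr_defaults))
  if (length(unknown)) stop("unknown qpcr config keys: ",
                            paste(unknown, collapse = ", "))
  qpcr <- utils::modifyList(qpcr_defaults, qpcr)
  cfg <- list(seed = as.integer(seed),
              genome_length = as.integer(genome_length),
              n_chroms = as.integer(n_chroms),
              dsb_sites = as.integer(dsb_sites),
              cut_efficiency = cut_efficiency,
              resected_fraction = resected_fraction,
              resection_mean = resection_mean,
              rejoined_fraction = rejoined_fraction,
              deletion_length = as.integer(deletion_length),
              open_peaks = open_peaks,
              footprint_sigma = footprint_sigma,
              preload_weight = preload_weight,
              dsb_induction_fold = dsb_induction_fold,
              adjacent_induction_fold = adjacent_induction_fold,
              ssdna_affinity = ssdna_affinity,
              fragment_len_range = as.integer(fragment_len_range),
              read_length = as.integer(read_length),
              n_fragments = as.integer(n_fragments),
              qpcr = qpcr)
  validate_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_config <- function(cfg) {
  probs <- c(cut_efficiency = cfg$cut_efficiency,
             resected_fraction = cfg$resected_fraction,
             rejoined_fraction = cfg$rejoined_fraction)
  stopifnot_named(
    "probabilities must lie in [0, 1]" = probs >= 0 & probs <= 1,
    "fragment_len_range must lie within [50, 2000] and be ordered" =
      length(cfg$fragment_len_range) == 2L &&
      cfg$fragment_len_range[1] >= 50L &&
      cfg$fragment_len_range[2] <= 2000L &&
      cfg$fragment_len_range[1] <= cfg$fragment_len_range[2],
    "read_length must not exceed the minimum fragment length" =
      cfg$read_length <= cfg$fragment_len_range[1],
    "resection_mean must be >= 1" = cfg$resection_mean >= 1,
    "dsb_induction_fold must be >= 1" = cfg$dsb_induction_fold >= 1,
    "deletion_length must be >= 0" = cfg$deletion_length >= 0L,
    "n_fragments must be positive" = cfg$n_fragments >= 1L,
    "genome_length must be positive" = cfg$genome_length >= 1L,
    "n_chroms must be >= 1" = cfg$n_chroms >= 1L,
    "open_peaks needs columns center, width, occupancy" =
      all(c("center", "width", "occupancy") %in% names(cfg$open_peaks)))
  edge <- cfg$fragment_len_range[2]
  if (length(cfg$dsb_sites) &&
      any(cfg$dsb_sites < edge |
          cfg$dsb_sites + 8L > cfg$genome_length - edge)) {
    stop("dsb_sites must lie more than the maximum fragment length (",
         edge, " bp) from the chromosome edges")
  }
  invisible(cfg)
}

ASISI_MOTIF <- "GCGATCGC"

#' Simulate a reference genome with planted recognition sites
#'
#' Generates uniform-random chromosomes, plants the AsiSI recognition motif
#' at each configured DSB coordinate, and scrubs any accidental occurrence of
#' the motif elsewhere (one base of each accidental hit is mutated) so that
#' the planted sites are exactly the scannable sites. Open-chromatin peaks
#' from the config are included in the site table as `open_chromatin`
#' records. Deterministic under the config seed.
#'
#' @param config a `simulation_config`.
#' @return list(genome = DNAStringSet, sites = `genomic_sites` with DSB and
#'   open_chromatin records).
#' @export
simulate_genome <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  seqs <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), config$genome_length,
                 replace = TRUE), collapse = "")
  }, "")
  # plant the motif on chromosome 1
  if (length(config$dsb_sites)) {
    s <- seqs[1]
    for (p in config$dsb_sites) {
      substr(s, p + 1L, p + 8L) <- ASISI_MOTIF
    }
    seqs[1] <- s
  }
  # scrub accidental motif occurrences (palindromic: forward scan suffices)
  planted <- config$dsb_sites
  for (iter in 1:10) {
    dirty <- FALSE
    for (i in seq_along(seqs)) {
      hits <- BiocGenerics::start(
        Biostrings::matchPattern(ASISI_MOTIF, Biostrings::DNAString(seqs[i]))) - 1L
      accidental <- if (i == 1L) setdiff(hits, planted) else hits
      if (length(accidental)) {
        dirty <- TRUE
        for (p in accidental) {
          # break the motif: flip its 5th base T -> A
          substr(seqs[i], p + 5L, p + 5L) <- "A"
        }
      }
    }
    if (!dirty) break
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms

  dsb <- if (length(config$dsb_sites)) {
    genomic_sites(chrom = "chr1",
                  start = config$dsb_sites,
                  end = config$dsb_sites + 8L,
                  cut = config$dsb_sites + 4L,
                  orientation = "*",
                  label = sprintf("dsb_%d", seq_along(config$dsb_sites)),
                  site_class = "DSB")
  } else NULL
  open <- if (nrow(config$open_peaks)) {
    pk <- config$open_peaks
    genomic_sites(chrom = "chr1",
                  start = as.integer(pk$center - pk$width / 2),
                  end = as.integer(pk$center + pk$width / 2),
                  cut = as.integer(pk$center),
                  orientation = "*",
                  label = sprintf("open_%d", seq_len(nrow(pk))),
                  site_class = "open_chromatin")
  } else NULL
  sites <- rbind(dsb, open)
  sites <- sort_sites(sites)
  class(sites) <- c("genomic_sites", "data.frame")
  list(genome = genome, sites = sites)
}

# Anchor each open peak to its nearest DSB cut if that cut lies at
# (min_dist, max_dist); returns the anchoring site index or NA per peak.
peak_anchor <- function(peak_centers, cuts, min_dist = 1500, max_dist = 50000) {
  if (length(cuts) == 0L || length(peak_centers) == 0L) {
    return(rep(NA_integer_, length(peak_centers)))
  }
  d <- abs(outer(peak_centers, cuts, "-"))
  j <- max.col(-d, ties.method = "first")
  dmin <- d[cbind(seq_along(peak_centers), j)]
  ifelse(dmin > min_dist & dmin < max_dist, j, NA_integer_)
}

#' Simulate fragments (molecules) under the cut/resection/occupancy model
#'
#' See the model description at the top of the file. Fragment truth records
#' carry the molecule's origin and template strand:
#' \describe{
#'   \item{dsDNA}{double-stranded; template_strand "both".}
#'   \item{ssDNA_left / ssDNA_right}{wholly inside a resected span; the
#'     retained 3'-terminated template is "+" left of the cut and "-" right
#'     of it.}
#'   \item{rejoined}{crosses a rejoined junction; may carry a deletion gap.}
#' }
#' Deterministic under the config seed (offset stream from simulate_genome's
#' so the two stages are independently reproducible).
#'
#' @param config a `simulation_config`.
#' @param genome DNAStringSet from [simulate_genome()] (used for chromosome
#'   names/lengths only).
#' @param sites `genomic_sites` table; rows with site_class "DSB" define the
#'   cuts.
#' @return a data.frame of class `fragment_truth`: chrom, start, end
#'   (0-based half-open, reference coordinates), template_strand
#'   ("+", "-", "both"), origin, deletion_start, deletion_end (NA if none).
#' @export
simulate_fragments <- function(config, genome, sites) {
  validate_config(config)
  set.seed(config$seed + 1L)
  n <- config$n_fragments
  chrom_names <- names(genome)
  chrom_len <- Biostrings::width(genome)
  G <- sum(chrom_len)
  cum_len <- cumsum(as.numeric(chrom_len))

  dsb <- sites[sites$site_class == "DSB", , drop = FALSE]
  cuts <- dsb$cut                       # all on chr1 by construction
  J <- length(cuts)
  pk <- config$open_peaks
  K <- nrow(pk)
  L <- config$resection_mean
  sig <- config$footprint_sigma
  q <- config$cut_efficiency

  # per-molecule state at each DSB
  cut_m <- matrix(stats::runif(n * J) < q, n, J)
  rej_m <- matrix(stats::runif(n * J) < config$rejoined_fraction, n, J) & cut_m
  res_m <- matrix(stats::runif(n * J) < config$resected_fraction, n, J) &
    cut_m & !rej_m
  sl <- matrix(1 + stats::rgeom(n * J, prob = 1 / L), n, J)
  sr <- matrix(1 + stats::rgeom(n * J, prob = 1 / L), n, J)
  if (J) {
    sl <- pmin(sl, matrix(cuts, n, J, byrow = TRUE))
    sr <- pmin(sr, matrix(chrom_len[1] - cuts, n, J, byrow = TRUE))
  }

  # occupancy mixture masses, one column per component
  # order: background | DSB_j ... | ssL_j ... | ssR_j ... | peak_k ...
  mass <- matrix(G, n, 1)
  if (J) {
    dsb_mass <- sweep(cut_m, 2,
                      (config$dsb_induction_fold - 1) * sqrt(2 * pi) * sig, "*")
    ssl_mass <- config$ssdna_affinity * sl * res_m
    ssr_mass <- config$ssdna_affinity * sr * res_m
    mass <- cbind(mass, dsb_mass, ssl_mass, ssr_mass)
  }
  if (K) {
    anchor <- peak_anchor(pk$center, cuts)
    base_pk <- config$preload_weight * pk$occupancy * sqrt(2 * pi) *
      (pk$width / 2)
    pk_mass <- matrix(base_pk, n, K, byrow = TRUE)
    for (k in seq_len(K)) {
      if (!is.na(anchor[k])) {
        boosted <- cut_m[, anchor[k]]
        pk_mass[boosted, k] <- pk_mass[boosted, k] *
          config$adjacent_induction_fold
      }
    }
    mass <- cbind(mass, pk_mass)
  }
  ncomp <- ncol(mass)
  cs <- mass %*% upper.tri(diag(ncomp), diag = TRUE)  # row-wise cumsum
  u <- stats::runif(n) * cs[, ncomp]
  comp <- 1L + as.integer(rowSums(cs < u))

  # draw the bound position x (0-based bp) and chromosome per fragment
  x <- numeric(n)
  chrom_i <- rep(1L, n)
  is_bg <- comp == 1L
  if (any(is_bg)) {
    g <- stats::runif(sum(is_bg)) * G
    ci <- findInterval(g, cum_len) + 1L
    chrom_i[is_bg] <- ci
    x[is_bg] <- g - c(0, cum_len)[ci]
  }
  if (J) {
    for (j in seq_len(J)) {
      idx <- comp == 1L + j
      if (any(idx)) x[idx] <- stats::rnorm(sum(idx), cuts[j], sig)
      idx <- comp == 1L + J + j          # ssDNA left span
      if (any(idx)) x[idx] <- cuts[j] - stats::runif(sum(idx)) * sl[idx, j]
      idx <- comp == 1L + 2L * J + j     # ssDNA right span
      if (any(idx)) x[idx] <- cuts[j] + stats::runif(sum(idx)) * sr[idx, j]
    }
  }
  if (K) {
    for (k in seq_len(K)) {
      idx <- comp == 1L + 3L * J + k
      if (any(idx)) x[idx] <- stats::rnorm(sum(idx), pk$center[k],
                                           pk$width[k] / 2)
    }
  }
  this_len <- chrom_len[chrom_i]
  x <- pmin(pmax(floor(x), 0), this_len - 1)

  # fragment placement: uniform length, uniform offset covering x
  lr <- config$fragment_len_range
  flen <- lr[1] + floor(stats::runif(n) * (lr[2] - lr[1] + 1L))
  start <- x - floor(stats::runif(n) * flen)
  end <- start + flen
  start <- pmax(start, 0)
  end <- pmin(end, this_len)

  # truncate at open (cut, unrejoined) breaks: fragments never cross them
  if (J) {
    on1 <- chrom_i == 1L
    for (j in seq_len(J)) {
      open_break <- cut_m[, j] & !rej_m[, j] & on1
      crosses <- open_break & start < cuts[j] & end > cuts[j]
      left <- crosses & x < cuts[j]
      right <- crosses & x >= cuts[j]
      end[left] <- cuts[j]
      start[right] <- cuts[j]
    }
  }

  origin <- rep("dsDNA", n)
  strand <- rep("both", n)
  del_s <- rep(NA_integer_, n)
  del_e <- rep(NA_integer_, n)
  d <- config$deletion_length
  if (J) {
    on1 <- chrom_i == 1L
    for (j in seq_len(J)) {
      # rejoined junction crossings (reference span widens by the deletion)
      rj <- rej_m[, j] & on1 & start < cuts[j] & end > cuts[j]
      if (any(rj)) {
        origin[rj] <- "rejoined"
        if (d > 0L) {
          del_s[rj] <- cuts[j]
          del_e[rj] <- cuts[j] + d
          end[rj] <- pmin(end[rj] + d, this_len[rj])
        }
      }
      # wholly inside a resected span -> single-stranded template
      inl <- res_m[, j] & on1 & start >= cuts[j] - sl[, j] & end <= cuts[j] &
        origin == "dsDNA"
      inr <- res_m[, j] & on1 & start >= cuts[j] & end <= cuts[j] + sr[, j] &
        origin == "dsDNA"
      origin[inl] <- "ssDNA_left"
      strand[inl] <- "+"
      origin[inr] <- "ssDNA_right"
      strand[inr] <- "-"
    }
  }

  keep <- end - start >= 1
  spans <- if (J) c(sl[res_m], sr[res_m]) else numeric()
  out <- data.frame(chrom = chrom_names[chrom_i],
                    start = as.integer(start), end = as.integer(end),
                    template_strand = strand, origin = origin,
                    deletion_start = del_s, deletion_end = del_e,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fragment_truth", "data.frame")
  # ground truth for the resection model: per-end resected span lengths
  attr(out, "resection_spans") <- spans
  out
}

# Resolve "both"-strand molecules into sequenced library strands: dsDNA
# yields either library strand with probability 1/2. Deterministic under the
# config seed. Returns the truth table with a resolved `strand` column.
resolve_library_strands <- function(fragments, config) {
  set.seed(config$seed + 2L)
  strand <- fragments$template_strand
  both <- strand == "both"
  strand[both] <- c("+", "-")[1L + (stats::runif(sum(both)) < 0.5)]
  fragments$strand <- strand
  fragments
}

# CIGAR for a read consuming `qlen` query bases from reference position
# `rstart` (0-based), with deletion gaps (0-based half-open matrix).
# Returns list(cigar, ref_end).
cigar_walk <- function(rstart, qlen, gap) {
  if (is.null(gap) || nrow(gap) == 0L) {
    return(list(cigar = paste0(qlen, "M"), ref_end = rstart + qlen))
  }
  gap <- gap[order(gap[, 1]), , drop = FALSE]
  ops <- character()
  pos <- rstart
  left <- qlen
  for (g in seq_len(nrow(gap))) {
    gs <- gap[g, 1]; ge <- gap[g, 2]
    if (ge <= pos) next
    if (left <= 0) break
    m <- min(left, gs - pos)
    if (m > 0) {
      ops <- c(ops, paste0(m, "M"))
      pos <- pos + m
      left <- left - m
    }
    if (left > 0 && pos == gs) {
      ops <- c(ops, paste0(ge - gs, "D"))
      pos <- ge
    }
  }
  if (left > 0) {
    ops <- c(ops, paste0(left, "M"))
    pos <- pos + left
  }
  # merge adjacent same-type ops is unnecessary here by construction
  list(cigar = paste(ops, collapse = ""), ref_end = pos)
}

# Reference start so that a read of qlen query bases ends exactly at ref_end.
ref_start_for_tail <- function(ref_end, qlen, gap) {
  if (is.null(gap) || nrow(gap) == 0L) return(ref_end - qlen)
  gap <- gap[order(-gap[, 1]), , drop = FALSE]
  pos <- ref_end
  left <- qlen
  for (g in seq_len(nrow(gap))) {
    gs <- gap[g, 1]; ge <- gap[g, 2]
    if (gs >= pos) next
    m <- min(left, pos - ge)
    if (m < 0) m <- 0
    pos <- pos - m
    left <- left - m
    if (left > 0 && pos == ge) pos <- gs
    if (left <= 0) break
  }
  pos - max(left, 0)
}

#' Write simulated fragments as a SAM file of proper read pairs
#'
#' Each fragment becomes one properly-paired PE read pair. Fragments whose
#' template is the + strand are emitted with SAM flags 99/147, - strand
#' fragments with flags 83/163; double-stranded ("both") fragments are
#' assigned either library strand with probability 1/2. Junction deletions
#' appear as CIGAR D gaps in any read overlapping them. Records are
#' coordinate-sorted and the header carries the sequence dictionary.
#'
#' @param fragments a `fragment_truth` table.
#' @param config the `simulation_config` used to generate them.
#' @param path output SAM path.
#' @param genome optional DNAStringSet; when supplied, read sequences are
#'   taken from the reference (gap bases excised), otherwise SEQ/QUAL are
#'   "*".
#' @return `path`, invisibly. The resolved per-fragment library strand is
#'   attached as attribute "strand".
#' @export
emit_sam <- function(fragments, config, path, genome = NULL) {
  fr <- resolve_library_strands(fragments, config)
  n <- nrow(fr)
  chroms <- unique(fr$chrom)
  if (!is.null(genome)) {
    sq_len <- stats::setNames(Biostrings::width(genome), names(genome))
    chroms <- names(genome)
  } else {
    sq_len <- tapply(fr$end, fr$chrom, max)
  }
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chroms,
                      as.integer(sq_len[chroms])))

  rl <- config$read_length
  gap_len <- ifelse(is.na(fr$deletion_start), 0L,
                    fr$deletion_end - fr$deletion_start)
  mol_len <- fr$end - fr$start - gap_len   # molecule (query-space) length
  qlen <- pmin(rl, mol_len)

  recs <- vector("list", n)
  for (i in seq_len(n)) {
    gap <- if (!is.na(fr$deletion_start[i])) {
      cbind(fr$deletion_start[i], fr$deletion_end[i])
    } else NULL
    fwd <- cigar_walk(fr$start[i], qlen[i], gap)
    rev_start <- ref_start_for_tail(fr$end[i], qlen[i], gap)
    rev <- cigar_walk(rev_start, qlen[i], gap)
    tlen <- fr$end[i] - fr$start[i]
    qname <- sprintf("frag_%07d", i)
    seq_f <- "*"; seq_r <- "*"; qual_f <- "*"; qual_r <- "*"
    if (!is.null(genome)) {
      ref <- genome[[fr$chrom[i]]]
      take <- function(rs, re) {
        s <- Biostrings::subseq(ref, rs + 1L, re)
        if (!is.null(gap)) {
          # excise gap bases from the aligned span
          segs <- c()
          pos <- rs
          keep <- character()
          gs <- gap[1, 1]; ge <- gap[1, 2]
          if (gs > rs && gs < re) {
            keep <- c(as.character(Biostrings::subseq(ref, rs + 1L, gs)),
                      if (ge < re) as.character(Biostrings::subseq(ref, ge + 1L, re)))
            return(paste(keep, collapse = ""))
          }
        }
        as.character(s)
      }
      seq_f <- take(fr$start[i], fwd$ref_end)
      seq_r <- take(rev_start, fr$end[i])
      qual_f <- strrep("I", nchar(seq_f))
      qual_r <- strrep("I", nchar(seq_r))
    }
    if (fr$strand[i] == "+") {
      # read1 forward at the left end (99), read2 reverse at the right (147)
      r1 <- sprintf("%s\t99\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s",
                    qname, fr$chrom[i], fr$start[i] + 1L, fwd$cigar,
                    rev_start + 1L, tlen, seq_f, qual_f)
      r2 <- sprintf("%s\t147\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s",
                    qname, fr$chrom[i], rev_start + 1L, rev$cigar,
                    fr$start[i] + 1L, -tlen, seq_r, qual_r)
    } else {
      # read1 reverse at the right end (83), read2 forward at the left (163)
      r1 <- sprintf("%s\t83\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s",
                    qname, fr$chrom[i], rev_start + 1L, rev$cigar,
                    fr$start[i] + 1L, -tlen, seq_r, qual_r)
      r2 <- sprintf("%s\t163\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s",
                    qname, fr$chrom[i], fr$start[i] + 1L, fwd$cigar,
                    rev_start + 1L, tlen, seq_f, qual_f)
    }
    recs[[i]] <- c(r1, r2)
  }
  body <- unlist(recs)
  # coordinate sort: by chrom then POS (field 4)
  pos <- as.integer(vapply(strsplit(body, "\t"), `[`, "", 4L))
  chv <- vapply(strsplit(body, "\t"), `[`, "", 3L)
  body <- body[order(match(chv, chroms), pos)]
  writeLines(c(header, body), path)
  out <- path
  attr(out, "strand") <- fr$strand
  invisible(out)
}

#' Simulate a restriction-protection qPCR Ct table
#'
#' For each configured amplicon distance x from a cut, the expected fraction
#' of molecules single-stranded at x is
#' f(x) = q * (1 - rejoined_fraction) * r * (1 - 1/L)^(x-1)
#' (cut, unrejoined, resected, and resection extending at least x). That
#' fraction is converted to a (mock, digested) Ct pair by inverting the
#' percent-ssDNA formula (see [percent_ssdna()]), ΔCt = 1 + log2(1/f - 0.5),
#' plus Gaussian Ct noise. f = 0 yields a digested Ct censored at 40 cycles,
#' which downstream QC flags as non-usable.
#'
#' @param config a `simulation_config`; `config$qpcr` holds distances,
#'   baseline Ct, noise sd and replicate count.
#' @param fractions optional explicit ssDNA fractions (one per distance)
#'   overriding the model-derived values.
#' @param path optional TSV output path.
#' @return a data.frame: amplicon, distance, ct_mock, ct_digested, replicate,
#'   with the true fractions as attribute "true_fraction".
#' @export
simulate_qpcr <- function(config, fractions = NULL, path = NULL) {
  validate_config(config)
  set.seed(config$seed + 3L)
  qp <- config$qpcr
  x <- qp$distances
  if (is.null(fractions)) {
    L <- config$resection_mean
    fractions <- config$cut_efficiency * (1 - config$rejoined_fraction) *
      config$resected_fraction * (1 - 1 / L)^(pmax(x, 1) - 1)
  }
  stopifnot_named("one ssDNA fraction per amplicon distance" =
                    length(fractions) == length(x),
                  "fractions must lie in [0, 1]" =
                    fractions >= 0 & fractions <= 1)
  nrep <- qp$n_replicates
  rows <- do.call(rbind, lapply(seq_along(x), function(i) {
    f <- fractions[i]
    ct_mock <- qp$baseline_ct + stats::rnorm(nrep, 0, qp$noise_sd)
    if (f == 0) {
      ct_dig <- rep(40, nrep)            # censored: no amplification
    } else {
      dct <- 1 + log2(1 / f - 0.5)
      ct_dig <- ct_mock + dct + stats::rnorm(nrep, 0, qp$noise_sd)
    }
    data.frame(amplicon = sprintf("amp_%dbp", as.integer(x[i])),
               distance = x[i], ct_mock = ct_mock, ct_digested = ct_dig,
               replicate = seq_len(nrep), stringsAsFactors = FALSE)
  }))
  attr(rows, "true_fraction") <- fractions
  if (!is.null(path)) {
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  rows
}
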