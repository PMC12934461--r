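# Aligned fragments -> filtered, strand-assigned, TMM-scaled binned coverage.
#
# A fragment table ("fragment_records") is a data.frame with columns
#   chrom, start, end   0-based half-open template span
#   flag1, flag2        SAM flags of the two reads
#   template_strand     "+", "-" or "unassigned" (from the flag pair)
#   proper_pair         logical
#   duplicate           logical (SAM duplicate flag)
#   gap_blocks          list column of two-column matrices (0-based
#                       half-open deletion intervals), possibly 0-row

#' Assign the template strand from a SAM flag pair
#'
#' Stranded library convention: the read-pair flag combination (99, 147)
#' marks a fragment sequenced from the + template strand and (83, 163) one
#' from the - strand; any other combination is unassigned. Order of the two
#' flags is immaterial.
#'
#' @param flag1,flag2 integer vectors of SAM flags, one pair per fragment.
#' @return character vector over {"+", "-", "unassigned"}.
#' @export
assign_template_strand <- function(flag1, flag2) {
  lo <- pmin(flag1, flag2)
  hi <- pmax(flag1, flag2)
  out <- rep("unassigned", length(lo))
  out[lo == 99L & hi == 147L] <- "+"
  out[lo == 83L & hi == 163L] <- "-"
  out
}

#' Read paired-end alignments into a fragment table
#'
#' Reads a SAM or BAM file (SAM is converted on the fly), pairing mates into
#' one record per fragment. Secondary and supplementary alignments and
#' mate-less reads are dropped; the drop tallies are attached as attribute
#' "tally". CIGAR D operations become `gap_blocks`.
#'
#' @param path SAM or BAM file.
#' @return a `fragment_records` data.frame (see file header), with attribute
#'   "tally" (named integer vector) and attribute "seqlengths".
#' @export
read_fragments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = TRUE)
  } else {
    bam <- path
  }
  total <- Rsamtools::countBam(bam)$records
  flag0 <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(what = "flag", flag = flag0)
  pairs <- GenomicAlignments::readGAlignmentPairs(bam, param = param,
                                                  strandMode = 0)
  first <- GenomicAlignments::first(pairs)
  last <- GenomicAlignments::last(pairs)
  n <- length(pairs)

  f1 <- S4Vectors::mcols(first)$flag
  f2 <- S4Vectors::mcols(last)$flag
  chrom <- as.character(GenomicAlignments::seqnames(first))
  start0 <- pmin(BiocGenerics::start(first), BiocGenerics::start(last)) - 1L
  end0 <- pmax(BiocGenerics::end(first), BiocGenerics::end(last))

  gaps_of <- function(aln) {
    rg <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      GenomicAlignments::cigar(aln), ops = "D",
      pos = BiocGenerics::start(aln))
    rg
  }
  g1 <- gaps_of(first)
  g2 <- gaps_of(last)
  gap_blocks <- lapply(seq_len(n), function(i) {
    r <- c(g1[[i]], g2[[i]])
    if (length(r) == 0L) return(matrix(numeric(), 0, 2))
    r <- IRanges::reduce(r)
    cbind(BiocGenerics::start(r) - 1L, BiocGenerics::end(r))
  })

  out <- data.frame(chrom = chrom, start = start0, end = end0,
                    flag1 = f1, flag2 = f2,
                    template_strand = assign_template_strand(f1, f2),
                    proper_pair = bitwAnd(f1, 2L) > 0L,
                    duplicate = bitwAnd(bitwOr(f1, f2), 1024L) > 0L,
                    stringsAsFactors = FALSE)
  out$gap_blocks <- gap_blocks
  class(out) <- c("fragment_records", "data.frame")
  attr(out, "tally") <- c(records_total = total,
                          records_paired = 2L * n,
                          records_dropped = total - 2L * n)
  attr(out, "seqlengths") <-
    GenomeInfoDb::seqlengths(GenomicAlignments::seqinfo(pairs))
  out
}

# Build fragment_records directly from simulator truth, bypassing SAM I/O.
# Applies the same library-strand resolution as emit_sam (deterministic
# under the config seed), so in-memory and file-based paths agree.
#' Convert simulator truth to fragment records without file I/O
#'
#' @param fragments a `fragment_truth` table from [simulate_fragments()].
#' @param config the generating `simulation_config`.
#' @return a `fragment_records` data.frame.
#' @export
fragments_to_records <- function(fragments, config) {
  fr <- resolve_library_strands(fragments, config)
  n <- nrow(fr)
  flag1 <- ifelse(fr$strand == "+", 99L, 83L)
  flag2 <- ifelse(fr$strand == "+", 147L, 163L)
  gap_blocks <- lapply(seq_len(n), function(i) {
    if (is.na(fr$deletion_start[i])) matrix(numeric(), 0, 2)
    else cbind(fr$deletion_start[i], fr$deletion_end[i])
  })
  out <- data.frame(chrom = fr$chrom, start = fr$start, end = fr$end,
                    flag1 = flag1, flag2 = flag2,
                    template_strand = fr$strand,
                    proper_pair = TRUE, duplicate = FALSE,
                    stringsAsFactors = FALSE)
  out$gap_blocks <- gap_blocks
  class(out) <- c("fragment_records", "data.frame")
  out
}

#' Filter fragment records (blacklist, duplicates, assay mode)
#'
#' Removal rules, in order:
#' \enumerate{
#'   \item blacklist: any fragment overlapping a blacklist interval by >= 1
#'     bp is removed;
#'   \item duplicates: fragments marked duplicate, plus coordinate
#'     duplicates — identical (chrom, start, end, template_strand) — with the
#'     first occurrence kept;
#'   \item atac mode only: fragments not in a proper pair, and fragments on
#'     excluded contigs (default the mitochondrial sequence).
#' }
#' Blacklist and duplicate removal commute, so the order is immaterial to
#' the survivor set. Per-rule removal counts are attached as attribute
#' "tally".
#'
#' @param records a `fragment_records` table.
#' @param blacklist optional `genomic_sites` table (or any data.frame with
#'   chrom/start/end) of intervals to exclude.
#' @param mode "chip" or "atac".
#' @param excluded_contigs contig names removed in atac mode.
#' @return the surviving records, with attribute "tally".
#' @export
filter_fragments <- function(records, blacklist = NULL,
                             mode = c("chip", "atac"),
                             excluded_contigs = "chrM") {
  mode <- match.arg(mode)
  n0 <- nrow(records)
  removed <- c(blacklist = 0L, duplicate = 0L, improper = 0L, contig = 0L)

  keep <- rep(TRUE, n0)
  if (!is.null(blacklist) && nrow(blacklist) > 0L) {
    frg <- GenomicRanges::GRanges(records$chrom,
                                  IRanges::IRanges(records$start + 1L,
                                                   records$end))
    blg <- GenomicRanges::GRanges(blacklist$chrom,
                                  IRanges::IRanges(blacklist$start + 1L,
                                                   blacklist$end))
    hit <- IRanges::overlapsAny(frg, blg)
    removed["blacklist"] <- sum(hit & keep)
    keep <- keep & !hit
  }
  key <- paste(records$chrom, records$start, records$end,
               records$template_strand)
  dup <- records$duplicate | duplicated(key)
  removed["duplicate"] <- sum(dup & keep)
  keep <- keep & !dup
  if (mode == "atac") {
    improper <- !records$proper_pair
    removed["improper"] <- sum(improper & keep)
    keep <- keep & !improper
    on_excl <- records$chrom %in% excluded_contigs
    removed["contig"] <- sum(on_excl & keep)
    keep <- keep & !on_excl
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fragment_records", "data.frame")
  attr(out, "tally") <- c(input = n0, removed, survivors = nrow(out))
  out
}

#' Compute a binned stranded coverage track
#'
#' Fragment-level (molecule-span) counting: each fragment adds its base-pair
#' overlap with each bin, divided by the bin size, to the bin of its template
#' strand; deletion gap blocks do not contribute. Fragments with an
#' unassigned template strand are excluded from both strand vectors. The
#' per-bin values are multiplied by `scale_factor`.
#'
#' @param records a `fragment_records` table, already filtered; must be on a
#'   single chromosome.
#' @param bin_size bin width, bp (default 50).
#' @param chrom_length track extent, bp; defaults to the largest fragment end
#'   rounded up to a bin boundary.
#' @param scale_factor multiplicative normalizer applied to the values.
#' @return an object of class `stranded_track`: list(chrom, bin_size,
#'   values_plus, values_minus (scaled), bp_plus, bp_minus (raw integer
#'   fragment-bp per bin, on which the strand partition is exact),
#'   scale_factor, n_fragments_used, chrom_length).
#' @export
compute_coverage <- function(records, bin_size = 50L, chrom_length = NULL,
                             scale_factor = 1) {
  if (bin_size <= 0L) stop("bin_size must be positive")
  if (scale_factor <= 0) stop("scale_factor must be positive")
  chroms <- unique(records$chrom)
  if (length(chroms) > 1L) {
    stop("compute_coverage expects a single chromosome; got: ",
         paste(chroms, collapse = ", "))
  }
  chrom <- if (length(chroms)) chroms else NA_character_
  used <- records$template_strand %in% c("+", "-")
  records <- records[used, , drop = FALSE]
  if (is.null(chrom_length)) {
    chrom_length <- if (nrow(records)) {
      as.integer(ceiling(max(records$end) / bin_size) * bin_size)
    } else bin_size
  }
  nbin <- as.integer(ceiling(chrom_length / bin_size))

  strand_cov <- function(sub) {
    if (nrow(sub) == 0L) return(numeric(nbin))
    # fragment span minus any gap blocks
    has_gap <- vapply(sub$gap_blocks, nrow, 0L) > 0L
    s <- sub$start[!has_gap]; e <- sub$end[!has_gap]
    if (any(has_gap)) {
      for (i in which(has_gap)) {
        g <- sub$gap_blocks[[i]]
        bounds <- c(sub$start[i], t(g), sub$end[i])
        seg_s <- bounds[seq(1, length(bounds), 2)]
        seg_e <- bounds[seq(2, length(bounds), 2)]
        ok <- seg_e > seg_s
        s <- c(s, seg_s[ok]); e <- c(e, seg_e[ok])
      }
    }
    e <- pmin(e, chrom_length)
    s <- pmax(s, 0)
    cov <- IRanges::coverage(IRanges::IRanges(s + 1L, e),
                             width = nbin * bin_size)
    v <- IRanges::Views(cov, start = seq(1L, nbin * bin_size, bin_size),
                        width = bin_size)
    as.numeric(IRanges::viewSums(v))     # integer fragment-bp per bin
  }
  bp <- strand_cov(records[records$template_strand == "+", , drop = FALSE])
  bm <- strand_cov(records[records$template_strand == "-", , drop = FALSE])
  structure(list(chrom = chrom, bin_size = as.integer(bin_size),
                 values_plus = bp / bin_size * scale_factor,
                 values_minus = bm / bin_size * scale_factor,
                 bp_plus = bp, bp_minus = bm,
                 scale_factor = scale_factor,
                 n_fragments_used = nrow(records),
                 chrom_length = as.integer(chrom_length)),
            class = "stranded_track")
}

#' Extract per-bin values from a stranded track
#'
#' @param track a `stranded_track`.
#' @param strand "+", "-" or "both" (sum of the two strands).
#' @return numeric vector of scaled per-bin values.
#' @export
track_values <- function(track, strand = c("both", "+", "-")) {
  strand <- match.arg(strand)
  switch(strand,
         "+" = track$values_plus,
         "-" = track$values_minus,
         both = track$values_plus + track$values_minus)
}

#' Rescale a stranded track to a new scale factor
#'
#' @param track a `stranded_track`.
#' @param scale_factor new multiplicative normalizer.
#' @return the rescaled track.
#' @export
rescale_track <- function(track, scale_factor) {
  if (scale_factor <= 0) stop("scale_factor must be positive")
  ratio <- scale_factor / track$scale_factor
  track$values_plus <- track$values_plus * ratio
  track$values_minus <- track$values_minus * ratio
  track$scale_factor <- scale_factor
  track
}

#' TMM scale factors for a samples-by-bins count matrix
#'
#' Trimmed-mean-of-M-values normalization of binned fragment counts: the
#' composition factors are computed by the standard TMM recipe (reference
#' sample chosen by 75th-percentile proximity to the mean, 30 percent M and
#' 5 percent A trimming, precision-weighted mean M), combined with
#' library-size ratios, inverted to multiplicative track scale factors and
#' rescaled so their geometric mean is 1. Applying the returned factor to
#' each sample's coverage equalizes depth and composition across samples.
#'
#' @param count_matrix numeric matrix, samples in rows, genomic bins in
#'   columns (row names are sample labels).
#' @return named numeric vector of per-sample scale factors, geometric mean
#'   1.
#' @export
tmm_scale_factors <- function(count_matrix) {
  if (is.null(dim(count_matrix)) || nrow(count_matrix) < 2L) {
    stop("tmm_scale_factors needs a matrix with >= 2 sample rows")
  }
  if (is.null(rownames(count_matrix))) {
    rownames(count_matrix) <- paste0("sample_", seq_len(nrow(count_matrix)))
  }
  zero <- rowSums(count_matrix) == 0
  if (any(zero)) {
    stop("sample(s) with all-zero bins: ",
         paste(rownames(count_matrix)[zero], collapse = ", "))
  }
  counts <- t(count_matrix)              # edgeR wants features x samples
  nf <- edgeR::calcNormFactors(counts, method = "TMM")
  lib <- colSums(counts)
  eff <- lib * nf                        # effective library sizes
  f <- 1 / eff
  f <- f / exp(mean(log(f)))             # geometric mean 1
  stats::setNames(f, rownames(count_matrix))
}

#' Bin fragment counts for normalization matrices
#'
#' Counts fragments per bin (by fragment midpoint) for each sample, the
#' coarse count matrix TMM normalization operates on.
#'
#' @param record_list named list of `fragment_records` tables (one per
#'   sample), single shared chromosome.
#' @param bin_size bin width, bp (default 10 kb).
#' @param chrom_length shared track extent, bp.
#' @return samples x bins integer matrix.
#' @export
count_matrix <- function(record_list, bin_size = 10000L,
                         chrom_length = NULL) {
  if (is.null(chrom_length)) {
    chrom_length <- max(vapply(record_list, function(r) max(r$end), 0))
  }
  nbin <- as.integer(ceiling(chrom_length / bin_size))
  m <- t(vapply(record_list, function(r) {
    mid <- (r$start + r$end) %/% 2L
    tabulate(pmin(mid %/% bin_size + 1L, nbin), nbins = nbin)
  }, integer(nbin)))
  rownames(m) <- names(record_list)
  m
}

#' Strand skew of a stranded track
#'
#' Raw skew is plus-strand minus minus-strand scaled coverage per bin — the
#' excess of reads from the + template on either side of a DSB. The
#' normalized skew (plus - minus) / (plus + minus + eps), eps = 1 scaled
#' count, is returned alongside; it is bounded on sparse bins.
#'
#' @param track a `stranded_track`.
#' @param eps pseudo-coverage for the normalized skew denominator.
#' @return object of class `skew_track`: list(chrom, bin_size, skew,
#'   skew_norm).
#' @export
skew_track <- function(track, eps = 1) {
  p <- track$values_plus
  m <- track$values_minus
  structure(list(chrom = track$chrom, bin_size = track$bin_size,
                 skew = p - m,
                 skew_norm = (p - m) / (p + m + eps),
                 chrom_length = track$chrom_length),
            class = "skew_track")
}

#' Combine tracks bin-wise (replicate mean or treatment-control subtraction)
#'
#' @param tracks list of `stranded_track`s on identical bins.
#' @param op "mean" (any number of replicates) or "subtract" (exactly two:
#'   first minus second).
#' @return a `stranded_track` with combined per-strand values
#'   (scale_factor 1; subtraction may produce negative values).
#' @export
combine_tracks <- function(tracks, op = c("mean", "subtract")) {
  op <- match.arg(op)
  stopifnot_named("combine_tracks needs at least one track" =
                    length(tracks) >= 1L)
  ref <- tracks[[1]]
  for (t in tracks[-1]) {
    if (!identical(t$bin_size, ref$bin_size) ||
        length(t$values_plus) != length(ref$values_plus) ||
        !identical(t$chrom, ref$chrom)) {
      stop("combine_tracks: tracks have mismatched binning")
    }
  }
  if (op == "subtract" && length(tracks) != 2L) {
    stop("subtract requires exactly two tracks (treatment, control)")
  }
  pick <- function(field) lapply(tracks, `[[`, field)
  comb <- function(vs) {
    if (op == "mean") Reduce(`+`, vs) / length(vs) else vs[[1]] - vs[[2]]
  }
  structure(list(chrom = ref$chrom, bin_size = ref$bin_size,
                 values_plus = comb(pick("values_plus")),
                 values_minus = comb(pick("values_minus")),
                 scale_factor = 1,
                 n_fragments_used =
                   sum(vapply(tracks, `[[`, 0, "n_fragments_used")),
                 chrom_length = ref$chrom_length),
            class = "stranded_track")
}

#' Write per-bin values as bedGraph
#'
#' @param values numeric per-bin vector.
#' @param chrom chromosome name.
#' @param bin_size bin width, bp.
#' @param path output path.
#' @param omit_zero drop zero bins (default TRUE).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(values, chrom, bin_size, path, omit_zero = TRUE) {
  start <- (seq_along(values) - 1L) * bin_size
  keep <- if (omit_zero) values != 0 else rep(TRUE, length(values))
  lines <- sprintf("%s\t%d\t%d\t%.6g", chrom, start[keep],
                   start[keep] + bin_size, values[keep])
  writeLines(lines, path)
  invisible(path)
}
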