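# Site prediction and interval-set management.
#
# A site table ("genomic sites") is a data.frame with columns
#   chrom        sequence name
#   start, end   0-based half-open coordinates (bp)
#   cut          single 0-based inter-base cut coordinate (DSB sites)
#   orientation  "+", "-" or "*" (unoriented; palindromic recognition sites)
#   label        free text
#   site_class   "DSB", "open_chromatin", "adjacent_open" or "other"
# All internal coordinates are BED-native (0-based half-open); conversion to
# the 1-based conventions of SAM/Bioconductor happens only at I/O boundaries.

#' Construct a genomic site table
#'
#' @param chrom character vector of sequence names.
#' @param start,end integer vectors, 0-based half-open.
#' @param cut 0-based inter-base cut coordinate; defaults to the interval
#'   midpoint.
#' @param orientation "+", "-" or "*".
#' @param label free-text site names.
#' @param site_class one of "DSB", "open_chromatin", "adjacent_open", "other".
#' @return a data.frame of class `genomic_sites`.
#' @export
genomic_sites <- function(chrom, start, end,
                          cut = start + (end - start) %/% 2,
                          orientation = "*",
                          label = paste0("site_", seq_along(chrom)),
                          site_class = "other") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   cut = as.integer(cut),
                   orientation = as.character(orientation),
                   label = as.character(label),
                   site_class = as.character(site_class),
                   stringsAsFactors = FALSE)
  validate_sites(df)
  class(df) <- c("genomic_sites", "data.frame")
  df
}

validate_sites <- function(df) {
  stopifnot_named(
    "site start must satisfy 0 <= start < end" =
      df$start >= 0L & df$start < df$end,
    "orientation must be one of +, -, *" =
      df$orientation %in% c("+", "-", "*"),
    "site_class must be DSB/open_chromatin/adjacent_open/other" =
      df$site_class %in% c("DSB", "open_chromatin", "adjacent_open", "other"))
  dsb <- df$site_class == "DSB" & !is.na(df$cut)
  stopifnot_named(
    "DSB cut coordinate must lie within [start, end]" =
      df$cut[dsb] >= df$start[dsb] & df$cut[dsb] <= df$end[dsb])
  invisible(df)
}

sort_sites <- function(df) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Scan reference sequences for an exact recognition motif
#'
#' Reports every occurrence of `motif` as a DSB site with the cut placed at
#' the motif midpoint (`start + floor(length/2)`), modelling blunt cleavage.
#' If the motif is palindromic (equal to its reverse complement, as for the
#' AsiSI site GCGATCGC) only forward-strand occurrences are reported, since a
#' reverse-strand scan would find the identical positions; such sites are
#' unoriented. For non-palindromic motifs both strands are scanned and the
#' occurrence strand is recorded in `orientation`. Overlapping occurrences
#' are all reported.
#'
#' @param refs reference sequences (see [as_reference_set()]).
#' @param motif recognition sequence over {A,C,G,T}, length >= 4. Ambiguity
#'   codes are rejected.
#' @return a `genomic_sites` table sorted by (chrom, start).
#' @export
scan_recognition_sites <- function(refs, motif) {
  refs <- as_reference_set(refs)
  motif <- toupper(motif)
  if (nchar(motif) < 4L) stop("motif must be at least 4 nt long")
  if (grepl("[^ACGT]", motif)) {
    stop("motif must contain only A/C/G/T; ambiguity codes are not supported")
  }
  pat <- Biostrings::DNAString(motif)
  rc <- as.character(Biostrings::reverseComplement(pat))
  palindromic <- identical(as.character(pat), rc)
  w <- nchar(motif)
  half <- w %/% 2L

  hit_frame <- function(pattern, orientation) {
    m <- Biostrings::vmatchPattern(pattern, refs)
    starts <- Biostrings::startIndex(m)
    do.call(rbind, lapply(seq_along(refs), function(i) {
      s <- starts[[i]]
      if (is.null(s) || length(s) == 0L) return(NULL)
      data.frame(chrom = names(refs)[i], start = s - 1L,
                 orientation = orientation, stringsAsFactors = FALSE)
    }))
  }

  hits <- hit_frame(motif, if (palindromic) "*" else "+")
  if (!palindromic) hits <- rbind(hits, hit_frame(rc, "-"))
  if (is.null(hits) || nrow(hits) == 0L) {
    return(genomic_sites(character(), integer(), integer(),
                         cut = integer(), orientation = character(),
                         label = character(), site_class = character()))
  }
  hits <- hits[order(hits$chrom, hits$start), , drop = FALSE]
  genomic_sites(chrom = hits$chrom,
                start = hits$start, end = hits$start + w,
                cut = hits$start + half,
                orientation = hits$orientation,
                label = sprintf("%s_%d", hits$chrom,
                                stats::ave(hits$start, hits$chrom,
                                           FUN = seq_along)),
                site_class = "DSB")
}

#' Predict Cas9 blunt cut sites for a protospacer
#'
#' Finds exact matches of a 20-nt protospacer with an adjacent NGG PAM and
#' places a blunt cut between protospacer positions 17 and 18, i.e. 3 bp on
#' the 5' side of the PAM — the standard SpCas9 convention. Both strands are
#' searched; reverse-strand matches are reported on reference coordinates
#' with `orientation = "-"` and mirrored cut arithmetic. A protospacer with
#' no PAM-adjacent match yields an empty table.
#'
#' @param protospacer 20-nt target sequence (the spacer, PAM excluded).
#' @param refs reference sequences (see [as_reference_set()]).
#' @return a `genomic_sites` table; `start`/`end` delimit the protospacer,
#'   `cut` is the blunt cut coordinate.
#' @export
cas9_cut_site <- function(protospacer, refs) {
  protospacer <- toupper(protospacer)
  if (nchar(protospacer) != 20L) stop("protospacer must be exactly 20 nt")
  if (grepl("[^ACGT]", protospacer)) stop("protospacer must be over {A,C,G,T}")
  refs <- as_reference_set(refs)

  out <- NULL
  for (i in seq_along(refs)) {
    seq_i <- as.character(refs[[i]])
    len <- nchar(seq_i)
    # + strand: protospacer at [p, p+20), PAM NGG at [p+20, p+23)
    m <- Biostrings::matchPattern(protospacer, refs[[i]])
    for (s in BiocGenerics::start(m)) {
      p <- s - 1L                       # 0-based
      if (p + 23L <= len &&
          substr(seq_i, p + 22L, p + 23L) == "GG") {
        out <- rbind(out, data.frame(chrom = names(refs)[i],
                                     start = p, end = p + 20L,
                                     cut = p + 17L, orientation = "+",
                                     stringsAsFactors = FALSE))
      }
    }
    # - strand: reverse complement of the protospacer on the + sequence,
    # PAM appears as CCN immediately 5' of the match
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(protospacer)))
    m2 <- Biostrings::matchPattern(rc, refs[[i]])
    for (s in BiocGenerics::start(m2)) {
      q <- s - 1L
      if (q - 3L >= 0L && substr(seq_i, q - 2L, q - 1L) == "CC") {
        # PAM-proximal end is the left end; cut 3 bp inside the protospacer
        out <- rbind(out, data.frame(chrom = names(refs)[i],
                                     start = q, end = q + 20L,
                                     cut = q + 3L, orientation = "-",
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    return(genomic_sites(character(), integer(), integer(),
                         cut = integer(), orientation = character(),
                         label = character(), site_class = character()))
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  genomic_sites(chrom = out$chrom, start = out$start, end = out$end,
                cut = out$cut, orientation = out$orientation,
                label = sprintf("cas9_%d", seq_len(nrow(out))),
                site_class = "DSB")
}

#' Read a BED6 file as a genomic site table
#'
#' BED6 dialect: name carries the site label, score is unused, strand carries
#' the orientation ("." maps to unoriented). The cut coordinate is not
#' representable in BED6 and is reconstructed as the interval midpoint, which
#' is exact for midpoint-cut sites (recognition-motif scans).
#'
#' @param path BED file path.
#' @param site_class class to assign to all records (default "other").
#' @return a `genomic_sites` table.
#' @export
read_sites <- function(path, site_class = "other") {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(genomic_sites(character(), integer(), integer(),
                         cut = integer(), orientation = character(),
                         label = character(), site_class = character()))
  }
  fields <- strsplit(lines[idx], "\t")
  parse_one <- function(f, lineno) {
    if (length(f) < 3L) {
      stop(sprintf("BED line %d: fewer than 3 fields", lineno))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("BED line %d: non-integer coordinates", lineno))
    }
    if (start >= end) {
      stop(sprintf("BED line %d: start (%d) must be < end (%d)",
                   lineno, start, end))
    }
    strand <- if (length(f) >= 6L) f[6] else "."
    if (!strand %in% c("+", "-", ".")) {
      stop(sprintf("BED line %d: bad strand '%s'", lineno, strand))
    }
    list(chrom = f[1], start = start, end = end,
         label = if (length(f) >= 4L) f[4] else ".",
         orientation = if (strand == ".") "*" else strand)
  }
  rows <- Map(parse_one, fields, idx)
  genomic_sites(chrom = vapply(rows, `[[`, "", "chrom"),
                start = vapply(rows, `[[`, 0L, "start"),
                end = vapply(rows, `[[`, 0L, "end"),
                orientation = vapply(rows, `[[`, "", "orientation"),
                label = vapply(rows, `[[`, "", "label"),
                site_class = site_class)
}

#' Write a genomic site table as BED6
#'
#' @param sites a `genomic_sites` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  validate_sites(sites)
  strand <- ifelse(sites$orientation == "*", ".", sites$orientation)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   sites$chrom, sites$start, sites$end, sites$label, strand)
  writeLines(lines, path)
  invisible(path)
}
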