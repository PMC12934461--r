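# Percent single-stranded DNA from restriction-protection qPCR.
#
# The assay digests genomic DNA with a restriction enzyme whose site lies
# inside each amplicon. Double-stranded template is cleaved and fails to
# amplify; single-stranded template (resected DNA) resists digestion. With
# amplification efficiency 2 per cycle and a heteroduplex correction for the
# mock template, the fraction of single-stranded molecules follows from the
# cycle-threshold shift dCt = Ct_digested - Ct_mock as
#
#     %ssDNA = 100 / (2^(dCt - 1) + 0.5)
#
# dCt = 0 (no protection lost) means fully single-stranded template (100%);
# as dCt grows the fraction decays toward 0. Records with either Ct above 35
# cycles are non-usable per assay QC.

#' Percent single-stranded DNA from a digested/mock Ct pair
#'
#' Vectorized. Records with either Ct above `max_ct` (default 35 cycles) are
#' non-usable and return NA, with the reasons attached as attribute
#' "excluded". Small negative dCt (to -0.5 cycles) is tolerated as technical
#' noise and clamped to 0; more negative dCt indicates an inverted assay and
#' is an error.
#'
#' @param ct_digested,ct_mock cycle thresholds (cycles).
#' @param max_ct usability cutoff, cycles.
#' @return numeric vector of %ssDNA in (0, 100], NA where non-usable.
#' @export
percent_ssdna <- function(ct_digested, ct_mock, max_ct = 35) {
  stopifnot_named(
    "ct vectors must have equal length" =
      length(ct_digested) == length(ct_mock),
    "Ct values must lie in (0, 45]" =
      c(ct_digested, ct_mock) > 0 & c(ct_digested, ct_mock) <= 45)
  usable <- ct_digested <= max_ct & ct_mock <= max_ct
  dct <- ct_digested - ct_mock
  if (any(dct[usable] < -0.5)) {
    stop("ct_digested more than 0.5 cycles below ct_mock: ",
         "digestion/mock assay inversion")
  }
  dct <- pmax(dct, 0)
  out <- 100 / (2^(dct - 1) + 0.5)
  out[!usable] <- NA_real_
  if (any(!usable)) {
    attr(out, "excluded") <- data.frame(
      index = which(!usable),
      reason = "non-usable: amplified above 35 cycles")
  }
  out
}

#' Aggregate replicate %ssDNA by amplicon distance
#'
#' Converts each usable (mock, digested) Ct pair to %ssDNA and aggregates
#' replicate-wise per amplicon distance. Amplicons with zero usable
#' replicates are reported with n = 0 and no mean. The exclusion log is
#' attached as attribute "excluded".
#'
#' @param ct_table data.frame with columns amplicon, distance, ct_mock,
#'   ct_digested, replicate (as written by [simulate_qpcr()] or read with
#'   [read_ct_table()]).
#' @param max_ct usability cutoff, cycles (default 35).
#' @return data.frame(distance, amplicon, mean_pct_ssdna, sd_pct_ssdna, n)
#'   ordered by distance.
#' @export
resection_profile <- function(ct_table, max_ct = 35) {
  need <- c("amplicon", "distance", "ct_mock", "ct_digested")
  missing_cols <- setdiff(need, names(ct_table))
  if (length(missing_cols)) {
    stop("ct_table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  pct <- percent_ssdna(ct_table$ct_digested, ct_table$ct_mock,
                       max_ct = max_ct)
  excluded <- attr(pct, "excluded")
  agg <- lapply(split(seq_len(nrow(ct_table)),
                      list(ct_table$amplicon, ct_table$distance),
                      drop = TRUE),
                function(idx) {
                  v <- pct[idx]
                  v <- v[!is.na(v)]
                  data.frame(distance = ct_table$distance[idx[1]],
                             amplicon = ct_table$amplicon[idx[1]],
                             mean_pct_ssdna = if (length(v)) mean(v)
                                              else NA_real_,
                             sd_pct_ssdna = if (length(v) > 1) stats::sd(v)
                                            else if (length(v) == 1) 0
                                            else NA_real_,
                             n = length(v))
                })
  out <- do.call(rbind, agg)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(excluded)) {
    excluded$amplicon <- ct_table$amplicon[excluded$index]
    attr(out, "excluded") <- excluded
  }
  out
}

#' Read a qPCR Ct table (TSV)
#'
#' @param path TSV with columns amplicon, distance, ct_mock, ct_digested,
#'   replicate.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
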