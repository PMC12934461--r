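# Site-centric statistics: metaprofiles, span/end/deletion classification,
# DSB-adjacent open-chromatin compilation, site-signal matrices,
# correlations, fold-changes.

#' Metaprofile of a track around a set of sites
#'
#' For each site, the window [cut - window, cut + window) is extracted from
#' the binned track (the cut is snapped to its containing bin). Sites with
#' orientation "-" are flipped before aggregation: the window is reversed
#' and, for stranded signals, the + and - strands are swapped (for skew,
#' flipping negates the values). Sites whose window extends off the track
#' are dropped with a message. The mean profile is the unweighted mean
#' across sites; matrix row order follows site order.
#'
#' @param track a `stranded_track` or `skew_track`.
#' @param sites a `genomic_sites` table (cut coordinates are used).
#' @param window half-window, bp; must be a multiple of the track bin size.
#' @param signal which signal to profile: "both", "plus", "minus" for a
#'   stranded track; "skew" or "skew_norm" for a skew track (defaults to the
#'   natural signal of the input).
#' @return list(matrix = sites x bins, profile = mean across sites,
#'   positions = bin-center offsets from the cut (bp), kept = logical vector
#'   marking which input sites contributed).
#' @export
metaprofile <- function(track, sites, window,
                        signal = NULL) {
  bs <- track$bin_size
  if (window %% bs != 0L) {
    stop("window must be a multiple of the track bin size (", bs, ")")
  }
  k <- window %/% bs
  is_skew <- inherits(track, "skew_track")
  if (is.null(signal)) signal <- if (is_skew) "skew" else "both"
  vals <- if (is_skew) {
    track[[match.arg(signal, c("skew", "skew_norm"))]]
  } else {
    switch(match.arg(signal, c("both", "plus", "minus")),
           both = track_values(track, "both"),
           plus = track$values_plus,
           minus = track$values_minus)
  }
  # for stranded signals at flipped sites, the opposite strand is read
  vals_flip <- if (is_skew) {
    -vals
  } else if (signal == "plus") {
    track$values_minus
  } else if (signal == "minus") {
    track$values_plus
  } else {
    vals
  }
  nbin <- length(vals)
  rows <- matrix(NA_real_, nrow(sites), 2L * k)
  keep <- rep(TRUE, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    if (!is.na(track$chrom) && sites$chrom[i] != track$chrom) {
      keep[i] <- FALSE
      next
    }
    b0 <- sites$cut[i] %/% bs
    lo <- b0 - k + 1L
    hi <- b0 + k
    if (lo < 1L || hi > nbin) {
      keep[i] <- FALSE
      next
    }
    v <- if (sites$orientation[i] == "-") {
      rev(vals_flip[lo:hi])
    } else {
      vals[lo:hi]
    }
    rows[i, ] <- v
  }
  if (any(!keep)) {
    message(sum(!keep), " site(s) dropped: window off the track")
  }
  rows <- rows[keep, , drop = FALSE]
  rownames(rows) <- sites$label[keep]
  positions <- (seq_len(2L * k) - k - 0.5) * bs
  list(matrix = rows,
       profile = if (nrow(rows)) colMeans(rows) else rep(NA_real_, 2L * k),
       positions = positions,
       kept = keep)
}

#' Classify fragments as spanning or ending at a cut site
#'
#' A fragment is \emph{ending} if either alignment terminus (its start or
#' end coordinate) lies within [cut - tol, cut + tol]; \emph{spanning} if it
#' covers that whole window and is not ending — deletion gap blocks do not
#' break the span; \emph{other} if it merely overlaps the window. The
#' reported fraction is ending / (ending + spanning), the share of
#' cut-proximal molecules whose ends sit at the break.
#'
#' @param records a `fragment_records` table.
#' @param site one site (single-row `genomic_sites` table or a list with
#'   `chrom` and `cut`).
#' @param tolerance bp tolerance around the cut (default 5).
#' @return object of class `span_counts`: list(n_spanning, n_ending,
#'   n_other, tolerance, fraction_ending).
#' @export
span_fraction <- function(records, site, tolerance = 5L) {
  cut <- site$cut[1]
  chrom <- site$chrom[1]
  r <- records[records$chrom == chrom, , drop = FALSE]
  lo <- cut - tolerance
  hi <- cut + tolerance
  ending <- (r$start >= lo & r$start <= hi) | (r$end >= lo & r$end <= hi)
  spanning <- r$start <= lo & r$end >= hi & !ending
  other <- (r$start <= hi & r$end >= lo) & !ending & !spanning
  n_end <- sum(ending)
  n_span <- sum(spanning)
  structure(list(n_spanning = n_span, n_ending = n_end,
                 n_other = sum(other), tolerance = tolerance,
                 fraction_ending = if (n_end + n_span > 0) {
                   n_end / (n_end + n_span)
                 } else NA_real_),
            class = "span_counts")
}

#' Histogram of repair-junction deletion lengths at a cut site
#'
#' Among fragments spanning the cut (gap blocks do not break the span), any
#' deletion gap overlapping [cut - tol, cut + tol] contributes its length.
#'
#' @param records a `fragment_records` table with `gap_blocks`.
#' @param site one site (needs `chrom` and `cut`).
#' @param tolerance bp tolerance around the cut (default 5).
#' @return data.frame(length, count), sorted by length; zero rows if no
#'   junction deletions are seen.
#' @export
detect_deletions <- function(records, site, tolerance = 5L) {
  cut <- site$cut[1]
  chrom <- site$chrom[1]
  r <- records[records$chrom == chrom & records$start < cut &
                 records$end > cut, , drop = FALSE]
  lens <- integer()
  for (g in r$gap_blocks) {
    if (nrow(g) == 0L) next
    ov <- g[, 1] <= cut + tolerance & g[, 2] >= cut - tolerance
    lens <- c(lens, as.integer(g[ov, 2] - g[ov, 1]))
  }
  if (length(lens) == 0L) {
    return(data.frame(length = integer(), count = integer()))
  }
  tab <- table(lens)
  data.frame(length = as.integer(names(tab)), count = as.integer(tab))
}

#' Compile DSB-adjacent open-chromatin sites
#'
#' Selects open-chromatin sites whose center-to-cut distance d to the
#' \emph{nearest} DSB satisfies min_dist < d < max_dist (default: more than
#' 1.5 kb but less than 50 kb up- or downstream), excluding any site whose
#' interval overlaps a [cut - min_dist, cut + min_dist] exclusion zone.
#' Each selected site is labeled `adjacent_open` and annotated with its
#' anchoring (nearest) DSB. Output is invariant to input order and to
#' duplicated DSB entries.
#'
#' @param dsb_sites `genomic_sites` table of cuts.
#' @param open_sites `genomic_sites` table of open-chromatin intervals.
#' @param min_dist,max_dist distance bounds, bp (defaults 1500 and 50000).
#' @return a `genomic_sites` table (site_class "adjacent_open") with an
#'   `anchor` column naming the nearest DSB.
#' @export
adjacent_open_sites <- function(dsb_sites, open_sites,
                                min_dist = 1500, max_dist = 50000) {
  dsb <- unique(dsb_sites[, c("chrom", "cut", "label")])
  keep <- logical(nrow(open_sites))
  anchor <- character(nrow(open_sites))
  for (i in seq_len(nrow(open_sites))) {
    cuts <- dsb[dsb$chrom == open_sites$chrom[i], , drop = FALSE]
    if (nrow(cuts) == 0L) next
    center <- (open_sites$start[i] + open_sites$end[i]) %/% 2L
    d <- abs(center - cuts$cut)
    j <- which.min(d)
    overlaps_zone <- any(open_sites$start[i] < cuts$cut + min_dist &
                           open_sites$end[i] > cuts$cut - min_dist)
    keep[i] <- d[j] > min_dist && d[j] < max_dist && !overlaps_zone
    anchor[i] <- cuts$label[j]
  }
  out <- open_sites[keep, , drop = FALSE]
  out$site_class <- rep("adjacent_open", nrow(out))
  out$anchor <- anchor[keep]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("genomic_sites", "data.frame")
  out
}

#' Site-by-sample signal matrix
#'
#' Mean scaled coverage (both strands) over [cut - window, cut + window) per
#' site, per sample track. All tracks must share binning.
#'
#' @param tracks named list of `stranded_track`s (names are sample labels).
#' @param sites `genomic_sites` table.
#' @param window half-window, bp; multiple of the shared bin size.
#' @return object of class `site_signal_matrix`: list(sites, samples,
#'   values, window_bp); `values` is sites x samples.
#' @export
site_signal_matrix <- function(tracks, sites, window) {
  stopifnot_named("tracks must be a named list" =
                    length(names(tracks)) == length(tracks))
  ref <- tracks[[1]]
  for (t in tracks) {
    if (!identical(t$bin_size, ref$bin_size) ||
        length(t$values_plus) != length(ref$values_plus)) {
      stop("site_signal_matrix: tracks have mismatched binning")
    }
  }
  vals <- vapply(tracks, function(t) {
    mp <- suppressMessages(metaprofile(t, sites, window, signal = "both"))
    v <- rep(NA_real_, nrow(sites))       # sites with off-track windows
    v[mp$kept] <- rowMeans(mp$matrix)
    v
  }, numeric(nrow(sites)))
  vals <- matrix(vals, nrow = nrow(sites),
                 dimnames = list(sites$label, names(tracks)))
  structure(list(sites = sites, samples = names(tracks), values = vals,
                 window_bp = window),
            class = "site_signal_matrix")
}

#' Pairwise Spearman correlation of site signals, with class labels
#'
#' Spearman rank correlation (average ranks on ties) between every pair of
#' sample columns, each pair labeled strong (rho >= 0.7), moderate
#' (0.5 <= rho < 0.7) or weak (rho < 0.5); zero-variance columns give
#' undefined correlations, reported as NA / "undefined".
#'
#' @param x a `site_signal_matrix` or a plain sites-by-samples matrix with
#'   >= 10 rows.
#' @return list(rho = correlation matrix, class = label matrix).
#' @export
correlate_sites <- function(x) {
  values <- if (inherits(x, "site_signal_matrix")) x$values else x
  if (nrow(values) < 10L) {
    stop("correlate_sites needs >= 10 sites")
  }
  rho <- suppressWarnings(stats::cor(values, method = "spearman"))
  cls <- matrix("undefined", nrow(rho), ncol(rho), dimnames = dimnames(rho))
  cls[!is.na(rho) & rho >= 0.7] <- "strong"
  cls[!is.na(rho) & rho >= 0.5 & rho < 0.7] <- "moderate"
  cls[!is.na(rho) & rho < 0.5] <- "weak"
  list(rho = rho, class = cls)
}

#' Per-site fold-change between two samples
#'
#' fold = (signal_b + pseudocount) / (signal_a + pseudocount) per site; the
#' summary is the median fold over sites. The pseudocount (default 1 scaled
#' count) bounds folds at empty sites.
#'
#' @param x a `site_signal_matrix` (or sites-by-samples matrix).
#' @param sample_a,sample_b column labels: denominator (reference) and
#'   numerator (treatment).
#' @param pseudocount non-negative pseudo-signal.
#' @return list(folds = named per-site vector, median_fold).
#' @export
fold_change <- function(x, sample_a, sample_b, pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  values <- if (inherits(x, "site_signal_matrix")) x$values else x
  for (s in c(sample_a, sample_b)) {
    if (!s %in% colnames(values)) stop("sample not in matrix: ", s)
  }
  folds <- (values[, sample_b] + pseudocount) /
    (values[, sample_a] + pseudocount)
  list(folds = folds, median_fold = stats::median(folds))
}
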