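# Config-driven orchestration: simulate -> tracks -> metrics -> resection,
# with a run manifest and fixed-name outputs. The package is library-first:
# this function (plus the bundled demo config) is the pipeline entry point.

#' Demo run configuration
#'
#' A desk-scale experiment: one 100-kb chromosome carrying three AsiSI-style
#' cut sites and eight pre-existing open-chromatin peaks, sequenced at 50,000
#' fragments per sample, with an uncut control ("noDSB") and an induced
#' sample ("DSB").
#'
#' @param seed integer seed governing every stochastic stage.
#' @param n_fragments fragments per sample.
#' @return a run-config list for [run_pipeline()].
#' @export
demo_config <- function(seed = 1L, n_fragments = 50000L) {
  list(
    seed = as.integer(seed),
    simulation = list(
      genome_length = 100000L,
      dsb_sites = c(20000L, 50000L, 80000L),
      open_peaks = data.frame(
        center = c(5000, 10000, 30000, 41000, 60000, 70000, 90000, 49200),
        width = 600,
        occupancy = c(2, 1, 4, 0.5, 3, 1.5, 2.5, 1)),
      n_fragments = as.integer(n_fragments),
      deletion_length = 9L),
    samples = list(noDSB = list(cut_efficiency = 0),
                   DSB = list()),
    bin_size = 50L,
    norm_bin_size = 10000L,
    window = 2500L,
    tolerance = 5L,
    mode = "chip",
    adjacent = list(min_dist = 1500, max_dist = 50000))
}

#' Run the full analysis pipeline on a simulated experiment
#'
#' Stages, mirroring a stranded DSB ChIP-seq workflow: simulate genome and
#' fragments per sample; filter fragments; compute binned stranded coverage;
#' TMM-normalize across samples; derive the skew track of the induced
#' sample; aggregate skew and coverage metaprofiles over cut sites; count
#' spanning/ending fragments and junction deletions per cut; compile
#' DSB-adjacent open-chromatin sites; build the site-by-sample signal
#' matrix with Spearman correlations and fold-changes; simulate and invert
#' the resection qPCR assay. Outputs use fixed names in `outdir`; a
#' `manifest.json` echoes every parameter with per-stage record tallies and
#' output checksums. Reruns with the same config are byte-identical.
#'
#' @param config run-config list (see [demo_config()] for the schema);
#'   unknown keys are rejected.
#' @param outdir output directory, created if absent.
#' @return invisibly, a list with the key in-memory results (sites, tracks,
#'   skew, metaprofile, span counts, signal matrix, correlations,
#'   fold-changes, resection profile, manifest).
#' @export
run_pipeline <- function(config, outdir) {
  known <- c("seed", "simulation", "samples", "bin_size", "norm_bin_size",
             "window", "tolerance", "mode", "adjacent")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$seed)) stop("config$seed is mandatory")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  defaults <- demo_config(config$seed)
  config <- utils::modifyList(defaults, config)

  base_cfg <- do.call(simulation_config,
                      c(list(seed = config$seed), config$simulation))

  # --- simulate: genome shared by all samples -------------------------------
  gen <- simulate_genome(base_cfg)
  sites <- gen$sites
  dsb <- sites[sites$site_class == "DSB", , drop = FALSE]
  open <- sites[sites$site_class == "open_chromatin", , drop = FALSE]
  write_sites(sites, file.path(outdir, "sites.bed"))

  sample_names <- names(config$samples)
  tallies <- list()
  records <- list()
  for (i in seq_along(sample_names)) {
    s <- sample_names[i]
    cfg_s <- do.call(simulation_config,
                     c(list(seed = config$seed + i),
                       utils::modifyList(config$simulation,
                                         config$samples[[s]])))
    fr <- simulate_fragments(cfg_s, gen$genome, sites)
    rec <- fragments_to_records(fr, cfg_s)
    rec <- filter_fragments(rec, mode = config$mode)
    tallies[[s]] <- attr(rec, "tally")
    records[[s]] <- rec
  }
  names(records) <- sample_names

  # --- tracks: coverage, TMM scaling, skew ----------------------------------
  cm <- count_matrix(records, bin_size = config$norm_bin_size,
                     chrom_length = base_cfg$genome_length)
  sf <- tmm_scale_factors(cm)
  tracks <- lapply(sample_names, function(s) {
    compute_coverage(records[[s]], bin_size = config$bin_size,
                     chrom_length = base_cfg$genome_length,
                     scale_factor = sf[[s]])
  })
  names(tracks) <- sample_names
  treated <- sample_names[length(sample_names)]
  sk <- skew_track(tracks[[treated]])
  write_bedgraph(tracks[[treated]]$values_plus, sk$chrom, config$bin_size,
                 file.path(outdir, "coverage_plus.bedGraph"))
  write_bedgraph(tracks[[treated]]$values_minus, sk$chrom, config$bin_size,
                 file.path(outdir, "coverage_minus.bedGraph"))
  write_bedgraph(sk$skew, sk$chrom, config$bin_size,
                 file.path(outdir, "skew.bedGraph"), omit_zero = TRUE)

  # --- metrics --------------------------------------------------------------
  mp_skew <- metaprofile(sk, dsb, window = config$window)
  mp_cov <- metaprofile(tracks[[treated]], dsb, window = config$window)
  utils::write.table(
    data.frame(position = mp_skew$positions, skew = mp_skew$profile,
               coverage = mp_cov$profile),
    file.path(outdir, "metaprofile.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  span_rows <- do.call(rbind, lapply(sample_names, function(s) {
    do.call(rbind, lapply(seq_len(nrow(dsb)), function(j) {
      sc <- span_fraction(records[[s]], dsb[j, ], config$tolerance)
      data.frame(sample = s, site = dsb$label[j],
                 n_spanning = sc$n_spanning, n_ending = sc$n_ending,
                 n_other = sc$n_other,
                 fraction_ending = sc$fraction_ending)
    }))
  }))
  utils::write.table(span_rows, file.path(outdir, "span_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  del_rows <- do.call(rbind, lapply(seq_len(nrow(dsb)), function(j) {
    h <- detect_deletions(records[[treated]], dsb[j, ], config$tolerance)
    if (nrow(h)) cbind(site = dsb$label[j], h) else NULL
  }))
  if (!is.null(del_rows)) {
    utils::write.table(del_rows, file.path(outdir, "deletions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  adj <- adjacent_open_sites(dsb, open,
                             min_dist = config$adjacent$min_dist,
                             max_dist = config$adjacent$max_dist)
  write_sites(adj, file.path(outdir, "adjacent_open.bed"))

  ssm <- site_signal_matrix(tracks, sites, window = config$window)
  utils::write.table(
    data.frame(site = rownames(ssm$values), ssm$values,
               check.names = FALSE),
    file.path(outdir, "site_signal.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  corr <- if (nrow(ssm$values) >= 10L) correlate_sites(ssm) else NULL
  if (!is.null(corr)) {
    utils::write.table(
      data.frame(sample = rownames(corr$rho), corr$rho, check.names = FALSE),
      file.path(outdir, "correlation.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  fc <- fold_change(ssm, sample_names[1], treated)
  utils::write.table(
    data.frame(site = names(fc$folds), fold = fc$folds,
               site_class = ssm$sites$site_class),
    file.path(outdir, "fold_change.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # --- resection ------------------------------------------------------------
  ct <- simulate_qpcr(base_cfg, path = file.path(outdir, "qpcr_ct.tsv"))
  resec <- resection_profile(ct)
  utils::write.table(resec, file.path(outdir, "resection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- manifest -------------------------------------------------------------
  out_files <- list.files(outdir, full.names = TRUE)
  out_files <- out_files[!grepl("manifest\\.json$", out_files)]
  manifest <- list(
    package = "dsbskew",
    version = as.character(utils::packageVersion("dsbskew")),
    parameters = config[setdiff(names(config), "simulation")],
    simulation = config$simulation[
      setdiff(names(config$simulation), "open_peaks")],
    open_peaks = config$simulation$open_peaks,
    scale_factors = as.list(sf),
    tallies = lapply(tallies, as.list),
    span_denominator = "ending / (ending + spanning)",
    checksums = as.list(tools::md5sum(out_files))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(sites = sites, tracks = tracks, skew = sk,
                 metaprofile = mp_skew, span_counts = span_rows,
                 signal_matrix = ssm, correlations = corr,
                 fold_change = fc, resection = resec,
                 scale_factors = sf, manifest = manifest))
}

#' Estimate resection length from a skew metaprofile
#'
#' The expected single-stranded-DNA coverage at distance x from a cut decays
#' as (1 - 1/L)^x under geometric resection, so the distance at which the
#' mean |skew| profile falls to half its maximum estimates L * ln(2). This
#' helper locates the half-maximum crossing on each side of the cut (linear
#' interpolation between bins, searching outward from the profile peak) and
#' returns the average crossing distance divided by ln(2).
#'
#' @param profile mean skew profile (from [metaprofile()] on a skew track).
#' @param positions bin-center offsets, bp.
#' @return estimated mean resection length, bp.
#' @export
estimate_resection_length <- function(profile, positions) {
  half_cross <- function(v, x) {
    # v: |skew| moving away from the cut; find where it first falls to
    # half its maximum, interpolating linearly
    pk <- which.max(v)
    vmax <- v[pk]
    if (vmax <= 0) return(NA_real_)
    below <- which(v < vmax / 2 & seq_along(v) > pk)
    if (length(below) == 0L) return(NA_real_)
    j <- below[1]
    x0 <- x[j - 1]; x1 <- x[j]
    v0 <- v[j - 1]; v1 <- v[j]
    x0 + (v0 - vmax / 2) / (v0 - v1) * (x1 - x0)
  }
  left <- positions < 0
  right <- positions > 0
  d_left <- half_cross(rev(abs(profile[left])), rev(-positions[left]))
  d_right <- half_cross(abs(profile[right]), positions[right])
  mean(c(d_left, d_right), na.rm = TRUE) / log(2)
}
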