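# dsbskew

Strand-resolved coverage and resection analysis at induced DNA
double-strand breaks (DSBs), for R.

## The problem

Site-specific nucleases — AsiSI (recognition site `GCGATCGC`) driven into
the nucleus on 4OHT treatment, or Cas9 ribonucleoproteins — cut the genome
at predictable coordinates. The broken ends are matured by 5'→3' resection,
which removes the 5'-terminated strand on each side and leaves a
3'-terminated single-stranded overhang: the **+ strand left of the cut, the
− strand right of it**. Library preparations that preserve template-strand
identity (read-pair flags 99/147 → + strand, 83/163 → − strand) therefore
make resection directly visible as a **strand skew**,

```
skew[b] = coverage_plus[b] − coverage_minus[b]
```

which is positive immediately left of a resected cut, negative immediately
right of it, antisymmetric around it, and decays with the resection-length
distribution — so the distance at which |skew| falls to half its maximum
estimates `L·ln 2` for geometric resection with mean `L`. Intact or
rejoined DNA contributes zero skew in expectation.

`dsbskew` is for genomicists analysing such stranded ChIP-seq / ATAC-seq
experiments. It provides:

- cut-site prediction (motif scanning with palindrome handling; Cas9 blunt
  cut 3 bp 5' of the NGG PAM) and BED6 site I/O;
- fragment-level SAM/BAM import, blacklist/duplicate/ATAC filtering,
  binned stranded coverage, TMM between-sample scaling, skew tracks,
  and track algebra (replicate mean, treatment − control);
- site-centric metrics: metaprofiles with orientation-aware flipping,
  spanning/ending fragment classification at cuts, repair-junction deletion
  detection from CIGAR gaps, DSB-adjacent open-chromatin compilation
  (1.5–50 kb from the nearest cut), site-by-sample signal matrices with
  Spearman class labels (strong ≥ 0.7 / moderate ≥ 0.5 / weak < 0.5) and
  median fold-changes;
- %ssDNA quantification from restriction-protection qPCR Ct tables,
  `%ssDNA = 100 / (2^(ΔCt−1) + 0.5)`, with the >35-cycle usability gate;
- a synthetic paired-end fragment simulator (PE150, 200–600 bp shear) with
  an explicit cut/resection/occupancy model and full ground truth, so every
  stage is testable without external data.

## Worked example

```r
library(dsbskew)
res <- run_pipeline(demo_config(seed = 1, n_fragments = 50000), "demo_out")
```

This simulates an uncut control ("noDSB") and an induced sample ("DSB") on
a 100-kb chromosome with three AsiSI-style cuts and eight open-chromatin
peaks, then runs the full track/metric/resection workflow. Key printed
results:

```r
res$scale_factors
#> noDSB   DSB
#> 1.014 0.986          # TMM factors, geometric mean 1

subset(res$span_counts, select = c(sample, site, fraction_ending))
#>   sample  site fraction_ending
#> 1  noDSB dsb_1          0.0500   # uncut: ends at the cut only by shear
#> 4    DSB dsb_1          0.7820   # induced: fragment ends pile up at cuts

estimate_resection_length(res$metaprofile$profile, res$metaprofile$positions)
#> 1517                  # bp; simulator truth is 1500

res$resection
#>   distance   amplicon mean_pct_ssdna sd_pct_ssdna n
#> 1      335  amp_335bp         48.702       1.4602 3
#> 2     1618 amp_1618bp         20.754       1.1511 3
#> 3     3500 amp_3500bp          6.032       0.2589 3
```

The ending fraction jumps from the random-shear baseline (~5%) to ~78% on
induction; the skew metaprofile recovers the simulated mean resection
length; %ssDNA decays with amplicon distance from the cut as the resection
survival function dictates. `demo_out/` holds stranded bedGraphs, the skew
track, metaprofile/span/correlation/fold-change TSVs, an adjacent-site BED,
the qPCR table, and a `manifest.json` echoing every parameter and filter
tally. Reruns are byte-identical.

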