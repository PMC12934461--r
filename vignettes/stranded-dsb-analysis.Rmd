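---
title: "Strand-resolved analysis of induced double-strand breaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-resolved analysis of induced double-strand breaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbskew)
```

## The measurement

Site-specific nucleases (AsiSI fused to an estrogen receptor, or Cas9
ribonucleoproteins) create double-strand breaks (DSBs) at known genomic
coordinates. DSB ends are matured by 5'→3' resection, which degrades the
5'-terminated strand on each side and leaves a 3'-terminated single-stranded
overhang: the + strand on the left of the cut and the − strand on the right.
A library preparation that preserves which template strand each fragment
derives from therefore sees an excess of + strand fragments immediately left
of a resected cut and of − strand fragments immediately right of it.

`dsbskew` quantifies this with the **skew track**

$$\mathrm{skew}_b \;=\; c^{+}_b - c^{-}_b,$$

the per-bin difference between + and − strand fragment coverage. Around a
resected cut the mean skew profile is positive on the left, negative on the
right, and antisymmetric; around intact or fully rejoined DNA it is zero in
expectation, with binomial sampling noise because a double-stranded molecule
enters the library from either strand with probability 1/2. A normalized
skew $(c^+ - c^-)/(c^+ + c^- + \varepsilon)$, $\varepsilon = 1$ scaled
count, is emitted alongside; the raw difference is the primary signal, the
normalized form is bounded on sparse bins.

The fragment-level pipeline mirrors the standard stranded ChIP-seq workflow:
read pairs with flags (99, 147) are assigned to the + template strand and
(83, 163) to the − strand; any other flag combination is left unassigned.
Fragments are filtered against a blacklist (≥ 1 bp overlap), coordinate
deduplicated (identical chrom/start/end/strand, first kept), and in ATAC
mode improper pairs and mitochondrial fragments are additionally removed.
Coverage is **molecule-centric**: each fragment contributes its base-pair
overlap per bin (gap blocks excluded), not its individual reads, because the
span/skew logic concerns template molecules. Between-sample scaling uses TMM
(trimmed mean of M-values) on a coarse binned count matrix; the returned
factors fold the TMM composition correction together with library-size
ratios and are rescaled to geometric mean 1, so that applying them
equalizes background coverage across samples even when a large fraction of
one sample's reads is concentrated at induced sites.

## The simulator and what it emulates

Every stage is testable against `simulate_fragments()`, an explicit
generative model. Per molecule:

1. each cut site fires with probability `cut_efficiency` (q); a cut is
   rejoined with probability `rejoined_fraction` (double-stranded again,
   optionally with a junction deletion appearing as a CIGAR `D` gap), and an
   unrejoined cut is resected with probability `resected_fraction` (r);
2. the resected span per end is `1 + Geometric(1/L)` bases with mean
   `resection_mean` (L). The geometric law is a modelling choice — memoryless
   per-base stopping of the nuclease — made because no distribution is
   implied by the data the package targets; it is a config choice, and the
   survival function $(1 - 1/L)^{x-1} \approx e^{-x/L}$ is what the
   half-max estimator below inverts;
3. a binding position is drawn from an occupancy mixture: uniform
   background, Gaussian open-chromatin peaks (peak density `preload_weight`
   × occupancy, boosted `adjacent_induction_fold`-fold when the peak's
   anchoring cut at 1.5–50 kb fires), a Gaussian footprint at each fired cut
   with total-over-background density `dsb_induction_fold` and width
   `footprint_sigma` (1000 bp models a broad clamp-like binder, 150 bp a
   narrow nuclease-like one), and a flat `ssdna_affinity` density on
   resected spans;
4. fragments take a uniform 200–600 bp shear length and are truncated at any
   open break — sheared molecules never cross an open DSB, so fully cut,
   unrejoined sites have zero spanning fragments; fragments wholly inside a
   resected span carry that span's single retained template strand,
   everything else is double-stranded and enters the library from either
   strand with probability 1/2.

Defaults (150 bp paired-end reads, 200–600 bp shear, ~25-fold DSB
induction, ~10-fold open-chromatin preloading, L = 1500 bp) reflect the
assayed system the package targets. `ssdna_affinity` has no measured value
and is a free parameter (default 5). The demo experiment uses one 100-kb
chromosome, three cut sites, and eight open-chromatin peaks with graded
occupancies (0.5–4), because accessibility peaks of equal strength would
make rank-based replicate concordance a coin flip.

What the simulator does **not** emulate: sequencing errors, PCR duplicates
beyond exact-coordinate collisions, mappability, chromatin-state
heterogeneity along the genome, inter-molecule correlation, or γ-H2AX-like
megabase domains. Passing tests therefore demonstrate the pipeline's
arithmetic and its ability to invert this model, not robustness to every
artifact of real libraries. One deliberate asymmetry: the SAM path reports a
junction deletion only when a read actually covers it (a 600 bp fragment
read 150 bp from each end can hide its junction), while the in-memory truth
path (`fragments_to_records()`) carries every gap; modal deletion detection
is unaffected.

## Estimators and numerical choices

**Resection length.** The expected single-stranded coverage at distance $x$
from a cut decays like the span survival function, so the distance at which
the mean |skew| profile falls to half its maximum estimates $L \ln 2$.
`estimate_resection_length()` searches outward from the profile peak (not
from $x = 0$: within a fragment length of the cut the profile is still
rising, because a fragment must fit wholly inside the span to carry its
strand), interpolates the half-max crossing linearly between bins, averages
the two sides, and divides by $\ln 2$. At L = 1500 bp and $10^5$ fragments
this recovers L within a few percent.

**Fold changes.** Per-site fold is $(v_b + pc)/(v_a + pc)$ with a
pseudocount of 1 scaled count (bounded folds at empty sites), summarized by
the median. Site signal is the **mean** scaled both-strand coverage over
±`window` around the cut, matching window-averaged profile plots. Because
the signal is a window mean of a Gaussian footprint, the measured fold
underestimates the peak induction fold by a computable factor
($1 + (F-1)\sqrt{2\pi}\sigma\,[\Phi(w/\sigma)-\Phi(-w/\sigma)]/2w$ against
background 1); the recovery test asserts against this closed form, under
conditions that isolate the parameter (scarless rejoining, no ssDNA
occupancy term), since break truncation and resected-span affinity are
separate modelled effects that also move coverage at the cut.

**Span/end classification.** A fragment *ends* at a cut if either terminus
falls within ±`tolerance` (default 5 bp — unstated by upstream protocols,
exposed in config); it *spans* if it covers the whole tolerance window and
is not ending. The reported fraction is ending / (ending + spanning): the
denominator is restricted to cut-proximal informative molecules, a choice
recorded in the run manifest. Uncut chromatin still shows a small nonzero
ending fraction from random shear (≈ $2 \cdot 2\,\mathrm{tol}$ / mean
fragment length relative to spanning).

**Adjacent open chromatin.** Open sites whose center lies more than 1.5 kb
but less than 50 kb from the *nearest* cut are labeled `adjacent_open`
(a site between two cuts counts once, anchored to the nearest); sites whose
interval overlaps any ±1.5 kb exclusion zone are removed.

**%ssDNA.** The restriction-protection qPCR converts the Ct shift between
digested and mock template into
$\%\mathrm{ssDNA} = 100 / (2^{\Delta C_t - 1} + 0.5)$: single-stranded
template resists digestion ($\Delta C_t = 0 \Rightarrow 100\%$), and the
$+0.5$ accounts for mock template entering the first cycle double-stranded.
$\Delta C_t$ down to −0.5 cycles is clamped to 0 as technical noise; lower
values indicate an inverted assay and raise an error. Records with either
Ct above 35 cycles are excluded as non-usable. The simulator inverts the
same formula, so the zero-noise round trip is exact to numerical precision;
an amplicon with zero single-stranded fraction emits a digested Ct censored
at 40 cycles, which the QC gate flags.

**Cut-site conventions.** Coordinates are 0-based half-open (BED-native)
internally, converted to 1-based only at SAM boundaries. AsiSI-style
cleavage is modeled blunt at the motif midpoint — the enzyme's 2-nt 3'
overhang is below the resolution of 150-bp reads and of binned profiles.
Cas9 cuts blunt between protospacer positions 17/18 (3 bp 5' of the NGG
PAM), the standard convention. Palindromic motifs are scanned on the
forward strand only (a reverse scan finds identical coordinates);
overlapping occurrences are all reported; ambiguity codes are rejected
rather than expanded. Genome-scale scans expose contig inclusion to the
caller rather than fixing an assembly scope.

**Determinism.** A single mandatory seed governs everything; each simulator
stage derives a fixed offset stream (genome: seed, fragments: seed + 1,
library-strand resolution: seed + 2, qPCR: seed + 3) so stages are also
independently reproducible. Pipeline reruns are byte-identical.

## Problem sizes

The bundled experiments run on a 100-kb single-chromosome genome with three
cut sites: 50k fragments for null-skew checks, 100k for skew-shape and
resection-length recovery (three seeds), 10–20k for classification tests.
These sizes put Monte-Carlo error comfortably inside the asserted
tolerances while keeping the whole suite near half a minute.

## Worked example

```{r, eval = FALSE}
library(dsbskew)
res <- run_pipeline(demo_config(seed = 1, n_fragments = 50000), "demo_out")
res$fold_change$median_fold        # all sites
res$resection                      # %ssDNA by amplicon distance
```

## Known limitations

Single-chromosome track containers (multi-chromosome inputs are processed
per contig); exact-match protospacer search only (no off-target scoring);
no peak calling or statistical testing of fold-changes; bigWig output is
not written (bedGraph is, and converts losslessly). The pipeline entry
point is the `run_pipeline()` function rather than a shell binary: the
package is library-first, and `scripts/acceptance.R` shows the scripted
form of the same workflow.
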