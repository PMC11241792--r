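---
title: "riboscope: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riboscope: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboscope)
```

riboscope analyses ribosome-profiling (Ribo-seq) and matched RNA-seq
libraries in transcript space. This vignette records the models it fits, the
tunable parameters that matter, what the synthetic-data generator does and
does not emulate, and the numerical decisions behind the implementation. All
objects flowing between stages are tidy tibbles; coordinates are 0-based and
half-open throughout, with 1-based formats (SAM) converted at the boundary.

## The measurement model

A translating ribosome protects a footprint of roughly 28–31 nt. The
position being decoded is summarized by the P-site: the first nucleotide of
the codon in the ribosome's peptidyl site, located at a characteristic
per-read-length offset downstream of the footprint's 5' end. Once P-sites
are localized, four families of statistics follow:

- **Periodicity.** Elongating ribosomes step in triplets, so CDS P-sites
  concentrate in reading frame 0. We summarize this as per-library frame
  fractions and as the metagene profile around the start codon, where
  periodicity appears as a 3-nt comb (dominant lag-3 autocorrelation).
- **Coding-feature distribution.** The share of P-sites in the 5'UTR, CDS
  and 3'UTR, compared against a "random positioning" expectation: each
  region's total length over the detected transcripts (those with at least
  one P-site) divided by total transcript length. The expectation therefore
  depends only on the annotation of the measured transcript population, not
  on counts. Whether the reference population should additionally be
  abundance-weighted is an open choice; we use the unweighted length model
  and note it here.
- **Codon occupancy.** For each ribosome site S in {E, P, A} (E = P-site
  codon − 3 nt, A = + 3 nt), a codon's occupancy index is its share of
  site-resolved signal divided by its usage frequency in the coding
  sequences. Values above 1 indicate slow decoding or stalling. Indices from
  two conditions are compared by Pearson correlation and per-codon robust
  z-scores on log2 index ratios, `z = (log2FC − median) / (1.4826 × MAD)`,
  with |z| ≥ 2.5 flagged as outlier codons.
- **Expression.** FPKM from its definition; median-of-ratios size factors; a
  negative-binomial Wald test for differential expression at the
  transcriptome (RNA) and translatome (RPF) levels; translation efficiency
  TE = normalized RPF / normalized RNA per condition, with
  ΔTE = log2(TE_trt / TE_ref); and the ΔΔCt calculation for qPCR
  validation data.

## P-site offset calibration

For each read length L, distances `d = cds_start − five_prime` are collected
for reads whose 5' end falls within `flank` (default 30) nt upstream of an
annotated start codon, restricted to `search_range` (default [6, 18],
intersected with [6, L−6]). The raw offset is the smallest d maximizing this
histogram; it is then frame-corrected among {raw−1, raw, raw+1} by choosing
the candidate maximizing the genome-wide frame-0 fraction of CDS P-sites,
ties to the smaller offset. Lengths with fewer than `min_support` (50)
supporting reads inherit the modal length's offset (`flag = "fallback"`).

Two deliberate simplifications: offsets are measured from the 5' extremity
only (not reconciled with a 3'-anchored estimate), and the frame correction
is a single global vote rather than per-transcript voting — both choices
favor a deterministic, low-depth-robust rule.

The identifying signal for the raw offset is the initiation pile-up: the
start codon carries the highest local density, so `d = offset` dominates
nearby in-frame distances. On data with no start-codon accumulation at all
(possible in the generator with `start_stop_boost = 1`) the histogram is
flat across in-frame distances and the offset is identifiable only up to a
multiple of 3; calibration tests that deliberately switch the pile-up off
therefore localize P-sites with the generator's true offsets rather than
re-estimating them, isolating the statistic under test from a calibration
step that is exercised separately.

The default `keep_range` of [25, 34] nt is wider than the canonical 28–31 so
that the reported footprint range is an observation, not an input.

## Codon occupancy details

- **Usage reference.** Usage is a codon tally over the CDSs of detected
  transcripts (start and stop included), unweighted by abundance — a
  documented simplification. For site-resolved indices the tally is
  additionally *availability-matched*: the first codon of a CDS can never
  occupy the A site (the P-site would sit in the UTR), nor the last the E
  site, so those positions are excluded from the reference for that site.
  Without this correction the A-site index of AUG is structurally depressed
  by ~25% at typical CDS lengths simply because every CDS begins with one.
- **Boundary rule.** Only P-sites inside the CDS contribute, and a site
  codon extending past a CDS boundary into a UTR is excluded.
- **No pseudocounts.** Codons with zero usage frequency are flagged
  undefined rather than smoothed, and dropped pairwise in comparisons.
- **Stop codons** are kept in tables and rankings (marked), but excluded
  from outlier statistics by default.
- **Replicate handling.** Within-condition libraries are pooled before
  indexing (per-library tables remain available); how the original analyses
  combined replicates is not documented, and pooling is the simpler default.
- **Degenerate comparisons.** If the MAD of log2 ratios is zero (e.g.
  identical tables), ratios equal to the median get z = 0 and the rest are
  flagged undefined rather than dividing by zero.

## Differential expression

Counts are normalized by median-of-ratios size factors (geometric-mean
centered; total-count fallback when no transcript is nonzero everywhere). A
per-transcript dispersion is estimated by the method of moments on
normalized counts — within-condition variance pooled across conditions,
`alpha = max(0, (s² − m) / m²)` — and shrunk 50/50 toward a mean–dispersion
trend `a0 + a1/m` fitted by least squares. The fit targets the mean of the
moment estimates deliberately: the estimator is mean-unbiased up to a mild
zero-truncation term, while median-based fits undershoot badly at 2
replicates because its sampling distribution is right-skewed.

The Wald statistic compares condition means on the log2 scale with
delta-method standard errors from the NB variance `m + alpha·m²` (a 0.5
pseudocount guards zero means). Because the shrunk dispersion still carries
estimation noise at few replicates, the statistic is referred to a t
distribution with `df = 8 × residual df` (16 at 2 vs 2) rather than the
normal; this df was fixed once by null-simulation calibration of the whole
moment/shrinkage pipeline (2,000 NB transcripts, mean 100, dispersion 0.05)
and approaches the normal as replication grows. Transcripts whose moment
dispersion hits zero with small counts fall back to an exact Poisson test.
BH-adjusted q-values are always reported; calls use the conventional raw-p
rule (|log2FC| > 1, p ≤ 0.05) by default, with `call_on = "qvalue"`
available. The down-regulation rule is applied symmetrically
(log2FC < −1).

Translatome DE runs on CDS-restricted footprint counts (footprints measure
elongation on the ORF); whether full-transcript counts were used in the
original analyses is unstated.

ΔTE inference propagates replicate variability of all four condition means
on the log scale by the delta method, with a Poisson floor on each variance
so zero-variance replicate pairs cannot produce infinite z. Note that
absolute TE is defined only up to a per-assay constant under any global
normalization; ΔTE is the depth-invariant quantity.

## The synthetic-data generator

`simulate_transcriptome()` builds transcripts with valid CDS geometry (AUG
start, stop end, no internal in-frame stop; uniform UTRs; internal codons
uniform over the 61 sense codons unless a composition table is supplied).
`simulate_library()` draws RPF reads by transcript → region → dwell-weighted
P-site codon → frame jitter → length → 5' end:

- transcript weight = molar abundance × fold change × feature length, with
  equal molar abundance by default so the pooled CDS codon positions are
  sampled uniformly and the null occupancy index is exactly 1 in
  expectation;
- region ~ `region_weights` (default 0.05/0.90/0.05); UTR positions are
  drawn where the footprint fits on the transcript, so the weights are the
  realized region distribution;
- within the CDS, position weights multiply the E/P/A dwell multipliers of
  the codons that would occupy those sites, times a `start_stop_boost`
  (default 3×) on the first and last codon emulating initiation queuing and
  termination pausing (no quantitative peak heights are available to
  calibrate this; set it to 1 for clean codon-occupancy calibration);
- the P-site stays in frame 0 with probability `inframe_fraction`
  (default 0.85), else shifts ±1 nt;
- length ~ `length_weights` (default 28:0.10, 29:0.60, 30:0.20, 31:0.10)
  and `five_prime = psite − offset[length]` (defaults 11/12/12/13).

RNA-seq reads are unstructured: uniform 5' ends at a fixed insert size.
Each library draws from its own stream seeded by `(seed, library_id)`, so
any library is reproducible in isolation. Ground truth (realized draws,
per-transcript counts, resample counts) rides along as an attribute, and
`write_dataset()` emits FASTA/TSV/JSON with a checksummed manifest.

A count-level companion, `simulate_counts()`, draws NB count matrices with
configurable dispersion, depth factors and fold changes; DE and TE
calibration use it directly, since those operate downstream of counting.

**What the generator does not emulate:** sequencing errors and quality,
adapter chemistry, rRNA contamination, multi-mapping ambiguity, isoform
structure, positional ramps beyond the start/stop boost, and
abundance-dependent detection. Passing recovery tests therefore demonstrates
correctness of the estimators under the stated sampling model, not
robustness to every artifact of real libraries.

### Null correlation vs null calibration

Two calibration regimes are deliberately distinct. Under a *flat* dwell null
(all multipliers 1) every codon index is ≈1, so the Pearson correlation
between two replicate index tables is near-degenerate — an essentially
constant vector has no variance to correlate. Replicate-correlation checks
therefore use a *condition-invariant dwell landscape*: per-codon lognormal
multipliers (sdlog 0.3, roughly the 1.5–2-fold spread between fast and slow
codons seen in real translatomes) shared by both libraries. That is the
regime real data live in, where between-condition correlations of 0.98–0.99
are typical; "null" here means no *differential* dwell. Index-level
calibration (all sense indices within 10% of 1) uses the flat null, where
that statement is meaningful.

## Problem sizes and tolerances

The test suite runs each recovery at the smallest size where the property is
stable: offset recovery and codon comparisons at 1–2 × 10⁵ reads per
library, frame/region recovery at ~10⁵ P-sites (±0.02 and ±0.01), null
index calibration at ≥ 2 × 10⁵ CDS P-sites ([0.9, 1.1]), outlier
calibration over 20 replicate pairs (≤ 5% flagged at z = 2.5), dwell
recovery within ±10% of the injected multiplier, DE calibration at 2,000
transcripts (type-I error in [0.03, 0.07] at p ≤ 0.05; power ≥ 0.8 on
4-fold spikes), and TE sign recovery ≥ 90% at 2 replicates. The full
pipeline is byte-for-byte deterministic given a seed, which the suite checks
by hashing reports from two runs.

## Known limitations

- Transcript-space only: no genome alignment, spliced projection, or
  isoform-level quantification.
- Offsets are global per read length; per-transcript heterogeneity and
  disome signatures are out of scope.
- Usage and the expected region model are abundance-unweighted.
- The NB test is a moment/Wald procedure tuned for small balanced designs;
  it is validated by simulation calibration, not by equivalence to any
  specific published tool.
- Readthrough-type claims are interpreted strictly through occupancy
  shifts; no flow modeling or stop-codon readthrough quantification is
  attempted.
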