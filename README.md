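# riboscope

Transcript-space analysis of ribosome-profiling (Ribo-seq) experiments with
matched RNA-seq, aimed at studies asking how a stress or treatment reshapes
translation: which codons ribosomes dwell on at the E/P/A sites, whether the
translatome responds as strongly as the transcriptome, and which transcripts
change translation efficiency. It was built around a two-condition plant
cold-stress design (control vs low temperature, two replicates per assay)
but the design is generic.

The package covers the full path from alignments to biology:

1. **P-site calibration** — per-read-length offsets estimated from the
   start-codon distance histogram with a frame-correction step; footprints
   are then converted to localized P-site records with frame, region
   (5'UTR/CDS/3'UTR) and E/P/A codons.
2. **Periodicity and metagene diagnostics** — frame fractions, start/stop
   metagene profiles (per-transcript-mean normalized), per-length
   periodicity heatmaps, and the observed-vs-expected P-site distribution
   across coding features, where the expectation is the random-positioning
   model over detected transcripts.
3. **Codon occupancy** — for site S ∈ {E, P, A} and codon c,

   `index_S(c) = occupancy_S(c) / usage(c)`

   with `occupancy_S(c)` the codon's share of site-resolved P-site signal
   and `usage(c)` its availability-matched frequency in the coding
   sequences. Conditions are compared by Pearson r and robust z-scores on
   log2 index ratios (`z = (log2FC − median) / (1.4826 × MAD)`, outliers at
   |z| ≥ 2.5).
4. **Expression** — FPKM, median-of-ratios size factors, a
   negative-binomial Wald test for transcriptome/translatome differential
   expression (`up: log2FC > 1, p ≤ 0.05`; `down` symmetric), translation
   efficiency `TE = RPF/RNA` with ΔTE inference, and ΔΔCt for qPCR
   validation.
5. **A ground-truth simulator** — Ribo-seq/RNA-seq libraries with known
   offsets, periodicity, region weights, per-codon E/P/A dwell multipliers
   and fold changes, so every estimator above is testable by parameter
   recovery. `simulate_counts()` provides the count-level NB companion for
   DE/TE calibration.

Everything takes and returns tidy tibbles; results chain with the pipe, and
fitted objects have `tidy()`/`glance()` methods plus `plot_*()` figures
(length spectrum, metagene, heatmap, region bars, codon ranking, occupancy
scatter, volcano). `run_pipeline()` drives all stages from a config (R list
or YAML) and writes stage TSVs plus a deterministic JSON/Markdown report.

## Worked example

Simulate a two-condition experiment in which the LT condition triples the
ribosome dwell on AAU codons at the E site, then recover all of it:

```r
library(riboscope)
library(dplyr)

cfg <- sim_config(reads_per_library = 5e4, seed = 7,
                  dwell = list(CK = list(), LT = list(E = c(AAU = 3))))
ds <- simulate_dataset(cfg)

rpf <- filter(ds$alignments, startsWith(library_id, "RPF"))
offsets <- estimate_offsets(rpf, ds$transcripts)
tidy(offsets)
#>   length offset n_support flag
#> 1     28     11       445 estimated
#> 2     29     12      3198 estimated
#> 3     30     12       942 estimated
#> 4     31     13       511 estimated

psites <- localize_psites(rpf, offsets, ds$transcripts)
frame_fractions(psites)
#>   library_id     n    f0     f1     f2
#> 1 RPF_CK_1   44942 0.852 0.0732 0.0747
#> 2 RPF_CK_2   44932 0.852 0.0770 0.0714
#> 3 RPF_LT_1   44949 0.849 0.0766 0.0741
#> 4 RPF_LT_2   44835 0.851 0.0742 0.0744

usE <- codon_usage(ds$transcripts, psites, site = "E")
cmp <- compare_occupancy(
  occupancy_index(filter(psites, grepl("CK", library_id)),
                  ds$transcripts, "E", usage = usE, group = "CK"),
  occupancy_index(filter(psites, grepl("LT", library_id)),
                  ds$transcripts, "E", usage = usE, group = "LT"))
filter(tidy(cmp), outlier)
#>   codon is_stop index_1 index_2 log2_ratio     z outlier direction
#> 1 AAU   FALSE      1.01    2.48       1.30  29.2 TRUE    up
```

The estimated offsets match the simulator's truth (11/12/12/13 nt), the
frame-0 fraction recovers the configured 85% periodicity, and AAU is the
single flagged E-site outlier: its index rises from ~1 to ~2.5, the diluted
image of the injected 3× dwell (15% of P-sites are off-frame by
construction). The same pipeline runs from files via
`run_pipeline(list(fasta = ..., annotation = ..., alignments = ...,
metadata = ..., seed = 1), out_dir = "out")`.

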