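test_that("simulated CDSs start with ATG, end with a stop, no internal stops", {
  cfg <- sim_config(n_transcripts = 1, cds_range = c(30, 30),
                    reads_per_library = 0, seed = 4)
  tx <- simulate_transcriptome(cfg)
  expect_equal(tx$cds_len, 30L)             # exactly 10 codons
  codons <- strsplit(substr(tx$sequence, tx$cds_start + 1, tx$cds_end),
                     "(?<=...)", perl = TRUE)[[1]]
  expect_equal(codons[1], "ATG")
  expect_true(codons[10] %in% c("TAA", "TAG", "TGA"))
  expect_false(any(codons[2:9] %in% c("TAA", "TAG", "TGA")))

  # the same holds across a default transcriptome (generator property)
  tx2 <- simulate_transcriptome(sim_config(n_transcripts = 40, seed = 9))
  starts <- substr(tx2$sequence, tx2$cds_start + 1, tx2$cds_start + 3)
  expect_true(all(starts == "ATG"))
  lasts <- substr(tx2$sequence, tx2$cds_end - 2, tx2$cds_end)
  expect_true(all(lasts %in% c("TAA", "TAG", "TGA")))
  expect_true(all(tx2$cds_len %% 3 == 0))
})

test_that("generation is deterministic given the seed, per library", {
  cfg <- sim_config(n_transcripts = 10, reads_per_library = 500, seed = 11)
  expect_identical(simulate_transcriptome(cfg), simulate_transcriptome(cfg))
  tx <- simulate_transcriptome(cfg)
  lib <- cfg$libraries[1, ]
  a1 <- simulate_library(tx, cfg, lib)
  a2 <- simulate_library(tx, cfg, lib)
  expect_identical(tibble::as_tibble(a1), tibble::as_tibble(a2))
  # a different library draws an independent stream
  b <- simulate_library(tx, cfg, cfg$libraries[2, ])
  expect_false(identical(a1$five_prime, b$five_prime))
})

test_that("a degenerate codon-composition table pins all internal codons", {
  cfg <- sim_config(n_transcripts = 3, cds_range = c(60, 60),
                    codon_composition = c(AAA = 1),
                    reads_per_library = 0, seed = 2)
  tx <- simulate_transcriptome(cfg)
  internal <- substr(tx$sequence, tx$cds_start + 4, tx$cds_end - 3)
  expect_true(all(grepl("^A+$", internal)))
})

test_that("forced in-frame construction: every read lands in frame 0", {
  meta <- library_metadata(assays = "RPF", conditions = "CK", replicates = 1)
  cfg <- sim_config(
    length_weights = c(`29` = 1), true_offsets = c(`29` = 12),
    inframe_fraction = 1, region_weights = c(utr5 = 0, cds = 1, utr3 = 0),
    libraries = meta, reads_per_library = 2000, seed = 5
  )
  tx <- simulate_transcriptome(cfg)
  aln <- simulate_library(tx, cfg, cfg$libraries[1, ])
  cds_start <- tx$cds_start[match(aln$transcript_id, tx$transcript_id)]
  expect_true(all((aln$five_prime + 12 - cds_start) %% 3 == 0))
})

test_that("dwell-null conditions yield exchangeable site codon spectra", {
  meta <- library_metadata(assays = "RPF", replicates = 1)
  cfg <- sim_config(reads_per_library = 5e4, seed = 8, start_stop_boost = 1,
                    libraries = meta)
  ds <- simulate_dataset(cfg)
  ps <- localize_psites(ds$alignments, true_offset_table(cfg),
                        ds$transcripts)
  for (site in c("E", "P", "A")) {
    ck <- site_codon_counts(dplyr::filter(ps, library_id == "RPF_CK_1"),
                            ds$transcripts, site)
    lt <- site_codon_counts(dplyr::filter(ps, library_id == "RPF_LT_1"),
                            ds$transcripts, site)
    keep <- ck$count + lt$count > 0
    p <- suppressWarnings(
      stats::chisq.test(cbind(ck$count[keep], lt$count[keep]))$p.value
    )
    expect_gt(p, 0.001)
  }
})

test_that("library spectra converge to the configured weights", {
  meta <- library_metadata(assays = "RPF", conditions = "CK", replicates = 1)
  cfg <- sim_config(reads_per_library = 1e5, seed = 6, libraries = meta)
  ds <- simulate_dataset(cfg)
  # read-length histogram within 0.01 of length_weights
  emp <- prop.table(table(ds$alignments$length))
  expect_lt(max(abs(emp[names(cfg$length_weights)] - cfg$length_weights)),
            0.01)
  # in-frame fraction within 0.02 of rho
  ps <- localize_psites(ds$alignments, true_offset_table(cfg),
                        ds$transcripts)
  f <- frame_fractions(ps)
  expect_lt(abs(f$f0 - cfg$inframe_fraction), 0.02)
  # all generated alignments respect transcript bounds
  tlen <- ds$transcripts$length[match(ds$alignments$transcript_id,
                                      ds$transcripts$transcript_id)]
  expect_true(all(ds$alignments$five_prime >= 0))
  expect_true(all(ds$alignments$five_prime + ds$alignments$length <= tlen))
})

test_that("an empty library is valid and dataset writing is reproducible", {
  cfg <- sim_config(n_transcripts = 5, reads_per_library = 0, seed = 3)
  ds <- simulate_dataset(cfg)
  expect_equal(nrow(ds$alignments), 0L)
  out1 <- withr::local_tempdir()
  out2 <- file.path(withr::local_tempdir(), "nested", "deeper")  # created
  m1 <- write_dataset(ds, out1)
  m2 <- write_dataset(ds, out2)
  # 1 FASTA + 1 annotation + 1 metadata + 8 libraries + ground truth
  expect_equal(length(m1$files), 12L)
  expect_identical(lapply(m1$files, `[[`, "md5"),
                   lapply(m2$files, `[[`, "md5"))
})

test_that("the NB count simulator honors depth factors and fold changes", {
  meta <- library_metadata(assays = "RNA")
  depth <- stats::setNames(c(1, 2, 1, 1), meta$library_id)
  sim <- simulate_counts(3000, meta, baseline_mean = 200, dispersion = 0.02,
                         depth_factors = depth, seed = 21)
  sf <- size_factors(sim$counts)
  est <- sf$size_factor / sf$size_factor[1]
  expect_lt(max(abs(est - depth / depth[1])), 0.05 * 2)
  lfc <- tibble::tibble(transcript_id = "g00001", assay = "RNA",
                        condition = "LT", log2fc = 2)
  sim2 <- simulate_counts(500, meta, 1000, 0.001, log2fc = lfc, seed = 1)
  lt <- rowMeans(sim2$counts[1, meta$library_id[meta$condition == "LT"]])
  ck <- rowMeans(sim2$counts[1, meta$library_id[meta$condition == "CK"]])
  expect_lt(abs(log2(lt / ck) - 2), 0.3)
})
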