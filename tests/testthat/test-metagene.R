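make_psites <- function(transcript_id, psite_pos, tx,
                        read_length = 29L, library_id = "lib1") {
  i <- match(transcript_id, tx$transcript_id)
  region <- ifelse(psite_pos < tx$cds_start[i], "utr5",
                   ifelse(psite_pos < tx$cds_end[i], "cds", "utr3"))
  tibble::tibble(
    transcript_id = transcript_id,
    psite_pos = as.integer(psite_pos),
    read_length = read_length,
    frame = ifelse(region == "cds",
                   (psite_pos - tx$cds_start[i]) %% 3L, NA_integer_),
    region = region,
    codon_E = NA_character_, codon_P = NA_character_,
    codon_A = NA_character_,
    library_id = library_id
  )
}

long_tx <- function() {
  transcript_models("t1", paste0(strrep("A", 100), "ATG", strrep("GGC", 98),
                                 "TAA", strrep("T", 100)),
                    cds_start = 100, cds_end = 400)
}

test_that("metagene profile: point mass, window cover, raw vs normalized", {
  tx <- long_tx()
  ps <- make_psites(rep("t1", 5), rep(100, 5), tx)
  prof <- metagene_profile(ps, tx, anchor = "start", normalization = "raw")
  expect_equal(prof$position, -30:60)
  expect_equal(prof$value[prof$position == 0], 5)
  expect_equal(sum(prof$value), 5)
  # per-transcript normalization rescales but keeps the support
  profn <- metagene_profile(ps, tx, anchor = "start")
  expect_equal(which(profn$value > 0), which(prof$value > 0))
  expect_error(metagene_profile(ps[0, ], tx), "empty")
})

test_that("stop-anchored windows use the first stop-codon nt as position 0", {
  tx <- long_tx()
  ps <- make_psites("t1", 397, tx)    # first nt of the TAA stop codon
  prof <- metagene_profile(ps, tx, anchor = "stop", normalization = "raw")
  expect_equal(prof$value[prof$position == 0], 1)
})

test_that("pure in-frame signal appears only at positions 0 mod 3", {
  meta <- library_metadata(assays = "RPF", conditions = "CK", replicates = 1)
  cfg <- sim_config(inframe_fraction = 1, reads_per_library = 3e4,
                    region_weights = c(utr5 = 0, cds = 1, utr3 = 0),
                    libraries = meta, seed = 17)
  ds <- simulate_dataset(cfg)
  ps <- localize_psites(ds$alignments, true_offset_table(cfg),
                        ds$transcripts)
  prof <- metagene_profile(ps, ds$transcripts, anchor = "start",
                           normalization = "raw")
  cds_side <- prof[prof$position >= 0, ]
  expect_true(all(cds_side$value[cds_side$position %% 3 != 0] == 0))
})

test_that("3-nt periodicity shows as dominant lag-3 autocorrelation", {
  meta <- library_metadata(assays = "RPF", conditions = "CK", replicates = 1)
  cfg <- sim_config(reads_per_library = 1e5, libraries = meta, seed = 23)
  ds <- simulate_dataset(cfg)
  ps <- localize_psites(ds$alignments, true_offset_table(cfg),
                        ds$transcripts)
  prof <- metagene_profile(ps, ds$transcripts, anchor = "start")
  v <- prof$value[prof$position >= 3 & prof$position <= 59]  # CDS side
  ac <- stats::acf(v, lag.max = 3, plot = FALSE)$acf[2:4]
  expect_gt(ac[3], ac[1])
  expect_gt(ac[3], ac[2])
})

test_that("frame fractions: degenerate, recovered, and uniform cases", {
  tx <- long_tx()
  ps0 <- make_psites(rep("t1", 10), 100 + 3 * (0:9), tx)
  f <- frame_fractions(ps0)
  expect_equal(c(f$f0, f$f1, f$f2), c(1, 0, 0))
  expect_error(frame_fractions(make_psites("t1", 5, tx)), "CDS")

  # uniform positions split evenly across frames
  set.seed(1)
  pos <- sample(100:397, 6e4, replace = TRUE)
  fu <- frame_fractions(make_psites(rep("t1", length(pos)), pos, tx))
  expect_true(all(abs(c(fu$f0, fu$f1, fu$f2) - 1 / 3) < 0.02))

  # generator rho recovered
  meta <- library_metadata(assays = "RPF", conditions = "CK", replicates = 1)
  cfg <- sim_config(reads_per_library = 5e4, libraries = meta, seed = 19)
  ds <- simulate_dataset(cfg)
  ps <- localize_psites(ds$alignments, true_offset_table(cfg),
                        ds$transcripts)
  expect_lt(abs(frame_fractions(ps)$f0 - 0.85), 0.02)
})

test_that("heatmap rows collapse to the raw profile and conserve counts", {
  tx <- long_tx()
  ps <- dplyr::bind_rows(
    make_psites(rep("t1", 4), c(100, 103, 100, 170), tx, read_length = 29L),
    make_psites(rep("t1", 3), c(106, 109, 250), tx, read_length = 30L)
  )
  hm <- periodicity_heatmap(ps, tx, anchor = "start")
  prof <- metagene_profile(ps, tx, anchor = "start", normalization = "raw")
  marg <- hm %>%
    dplyr::group_by(position) %>%
    dplyr::summarise(value = sum(count), .groups = "drop")
  expect_equal(marg$value, prof$value)
  # row sums equal the per-length totals inside the window
  totals <- hm %>%
    dplyr::group_by(read_length) %>%
    dplyr::summarise(n = sum(count), .groups = "drop")
  expect_equal(totals$n[totals$read_length == 29], 3L)  # 170 is outside window
  expect_equal(totals$n[totals$read_length == 30], 2L)  # 250 is outside window
  # a single read length collapses to a one-row heatmap equal to the profile
  hm29 <- periodicity_heatmap(ps[ps$read_length == 29L, ], tx,
                              anchor = "start")
  expect_equal(sort(unique(hm29$read_length)), 29L)
})

test_that("region distribution: symmetry, degeneracy, and the null model", {
  tx <- transcript_models("tEq", paste0(strrep("A", 100), "ATG",
                                        strrep("CGT", 31), "TGA",
                                        strrep("T", 100)),
                          cds_start = 100, cds_end = 199)
  # equal region lengths (~100 nt each) give an expected triple near 1/3
  ps <- make_psites(rep("tEq", 6), c(110, 120, 130, 140, 150, 160), tx)
  rd <- region_distribution(ps, tx)
  expect_equal(rd$expected, rep(1 / 3, 3), tolerance = 0.01)
  expect_equal(rd$observed, c(0, 1, 0))          # all P-sites in the CDS
  expect_equal(sum(rd$observed), 1)
  expect_equal(sum(rd$expected), 1)

  # the expected triple depends only on the annotation of detected
  # transcripts, not on counts
  ps2 <- make_psites(rep("tEq", 2), c(5, 250), tx, library_id = "lib2")
  rd2 <- region_distribution(ps2, tx)
  expect_equal(rd2$expected, rd$expected)
})

test_that("region weights are recovered from generated libraries", {
  meta <- library_metadata(assays = "RPF", conditions = "CK", replicates = 1)
  cfg <- sim_config(reads_per_library = 4e4, libraries = meta, seed = 29)
  ds <- simulate_dataset(cfg)
  ps <- localize_psites(ds$alignments, true_offset_table(cfg),
                        ds$transcripts)
  rd <- region_distribution(ps, ds$transcripts)
  expect_lt(max(abs(rd$observed - c(0.05, 0.90, 0.05))), 0.02)
})
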