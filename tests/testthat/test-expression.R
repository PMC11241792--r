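test_that("fpkm follows its closed form and is depth-scale invariant", {
  counts <- tibble::tibble(transcript_id = c("t1", "t2"),
                           libA = c(10L, 0L),
                           libB = c(20L, 999990L))
  lens <- tibble::tibble(transcript_id = c("t1", "t2"),
                         length = c(1000L, 500L))
  # force library total 1e6 for the closed-form check
  counts$libA[2] <- 999990L
  f <- fpkm(counts, lens)
  expect_equal(f$libA[1], 10)                 # 10 * 1e9 / (1000 * 1e6)
  zero <- dplyr::mutate(counts, libA = c(0L, 10L))
  expect_equal(fpkm(zero, lens)$libA[1], 0)
  # doubling every count of a library leaves its FPKM column unchanged
  doubled <- dplyr::mutate(counts, libA = libA * 2L)
  expect_equal(fpkm(doubled, lens)$libA, f$libA)
  expect_error(fpkm(dplyr::mutate(counts, libA = 0L), lens), "zero library")
})

test_that("size factors: identity, depth ratio, centering, fallback", {
  counts <- tibble::tibble(transcript_id = paste0("t", 1:50),
                           a = rpois(50, 100) + 1L)
  counts$b <- counts$a
  sf <- size_factors(counts)
  expect_equal(sf$size_factor, c(1, 1))
  counts$b <- counts$a * 2L
  sf2 <- size_factors(counts)
  expect_equal(sf2$size_factor[2] / sf2$size_factor[1], 2, tolerance = 1e-6)
  expect_equal(exp(mean(log(sf2$size_factor))), 1, tolerance = 1e-6)
  # no transcript nonzero everywhere -> total-count fallback with warning
  disjoint <- tibble::tibble(transcript_id = c("t1", "t2"),
                             a = c(10L, 0L), b = c(0L, 30L))
  expect_warning(sf3 <- size_factors(disjoint), "total-count")
  expect_equal(sf3$size_factor[2] / sf3$size_factor[1], 3)
})

test_that("identical condition profiles are never called differential", {
  meta <- library_metadata(assays = "RNA")
  set.seed(2)
  base <- rpois(100, 80)
  counts <- tibble::tibble(transcript_id = paste0("t", 1:100))
  for (lib in meta$library_id) counts[[lib]] <- base
  de <- de_test(counts, meta, assay = "RNA")
  expect_true(all(de$log2fc == 0))
  expect_true(all(de$call == "ns"))
  # single replicate is a hard error
  meta1 <- meta[meta$replicate == 1, ]
  expect_error(de_test(counts[, c("transcript_id", meta1$library_id)],
                       meta1, assay = "RNA"), "replicate")
})

test_that("de_test is equivariant under transcript relabeling", {
  meta <- library_metadata(assays = "RNA")
  sim <- simulate_counts(300, meta, 100, 0.05, seed = 41)
  de <- de_test(sim$counts, meta, assay = "RNA")
  perm <- sample(nrow(sim$counts))
  de_p <- de_test(sim$counts[perm, ], meta, assay = "RNA")
  expect_equal(de_p$pvalue[match(de$transcript_id, de_p$transcript_id)],
               de$pvalue)
})

test_that("null p-values are calibrated and spiked signals are found", {
  meta <- library_metadata(assays = "RNA")
  sim <- simulate_counts(1500, meta, 100, 0.05, seed = 3)
  de <- de_test(sim$counts, meta, assay = "RNA")
  expect_gt(mean(de$pvalue <= 0.05), 0.02)
  expect_lt(mean(de$pvalue <= 0.05), 0.09)
  expect_lt(suppressWarnings(
    stats::ks.test(de$pvalue, "punif")$statistic), 0.06)

  spike <- tibble::tibble(transcript_id = sprintf("g%05d", 1:75),
                          assay = "RNA", condition = "LT", log2fc = 2)
  sim2 <- simulate_counts(1500, meta, 100, 0.05, log2fc = spike, seed = 4)
  de2 <- de_test(sim2$counts, meta, assay = "RNA",
                 conditions = c("CK", "LT"))
  expect_gte(mean(de2$call[1:75] == "up"), 0.8)
})

test_that("fold-change estimates agree with edgeR on spiked data", {
  meta <- library_metadata(assays = "RNA")
  spike <- tibble::tibble(transcript_id = sprintf("g%05d", 1:50),
                          assay = "RNA", condition = "LT",
                          log2fc = rep(c(2, -2), 25))
  sim <- simulate_counts(800, meta, 150, 0.05, log2fc = spike, seed = 6)
  de <- de_test(sim$counts, meta, assay = "RNA", conditions = c("CK", "LT"))
  m <- as.matrix(sim$counts[, meta$library_id])
  rownames(m) <- sim$counts$transcript_id
  y <- edgeR::DGEList(m, group = meta$condition)
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateDisp(y, model.matrix(~ meta$condition))
  et <- edgeR::exactTest(y, pair = c("CK", "LT"))
  expect_gt(cor(de$log2fc, et$table$logFC), 0.95)
  top_ours <- de$transcript_id[order(de$pvalue)][1:50]
  top_edger <- rownames(et$table)[order(et$table$PValue)][1:50]
  expect_gt(length(intersect(top_ours, top_edger)) / 50, 0.8)
})

test_that("translation efficiency: identity, response, depth invariance", {
  meta <- library_metadata()
  counts <- tibble::tibble(transcript_id = paste0("t", 1:20))
  set.seed(7)
  base <- rpois(20, 200)
  for (lib in meta$library_id) counts[[lib]] <- base
  te <- translation_efficiency(counts, meta, conditions = c("CK", "LT"))
  expect_equal(unname(te$te_ref), rep(1, 20))
  expect_equal(unname(te$delta_te), rep(0, 20))

  # doubling RPF in LT for a minority of transcripts doubles their TE there
  # (a change applied to every transcript would be absorbed by the
  # median-of-ratios normalization, as in any global-scaling scheme)
  c2 <- counts
  for (lib in meta$library_id[meta$assay == "RPF" &
                                meta$condition == "LT"]) {
    c2[[lib]][1:3] <- base[1:3] * 2L
  }
  te2 <- translation_efficiency(c2, meta, conditions = c("CK", "LT"))
  expect_equal(unname(te2$delta_te[1:3]), rep(1, 3), tolerance = 0.05)
  expect_equal(unname(te2$delta_te[4:20]), rep(0, 17), tolerance = 0.05)

  # scaling one library's counts shifts TE by a shared constant only:
  # delta-TE is exactly depth-invariant
  c3 <- counts
  c3[["RNA_CK_1"]] <- c3[["RNA_CK_1"]] * 5L
  te3 <- translation_efficiency(c3, meta, conditions = c("CK", "LT"))
  expect_equal(unname(te3$delta_te), unname(te$delta_te))
  expect_equal(stats::sd(log(te3$te_ref / te$te_ref)), 0, tolerance = 1e-12)

  # zero RNA means flag TE undefined
  c4 <- counts
  for (lib in meta$library_id[meta$assay == "RNA"]) c4[[lib]][1] <- 0L
  te4 <- translation_efficiency(c4, meta, conditions = c("CK", "LT"))
  expect_false(te4$defined[1])
})

test_that("perturbed translation efficiency recovers the sign of the shift", {
  meta <- library_metadata()
  lfc <- tibble::tibble(transcript_id = sprintf("g%05d", 1:50),
                        assay = "RPF", condition = "LT",
                        log2fc = rep(c(1, -1), 25))
  sim <- simulate_counts(600, meta, 100, 0.05, log2fc = lfc, seed = 43)
  te <- translation_efficiency(sim$counts, meta, conditions = c("CK", "LT"))
  expect_gte(mean(sign(te$delta_te[1:50]) == sign(lfc$log2fc)), 0.9)
})

test_that("ddCt arithmetic matches the closed form", {
  # ddCt = 0 -> RQ = 1
  d0 <- ddct(c(20, 20, 20, 20), c(15, 15, 15, 15), c("CK", "CK", "LT", "LT"))
  expect_equal(attr(d0, "ddct"), 0)
  expect_equal(attr(d0, "rq"), 1)
  # target 20 -> 23 with stable reference: ddCt = 3, RQ = 1/8
  d1 <- ddct(c(20, 20, 23, 23), c(15, 15, 15, 15), c("CK", "CK", "LT", "LT"))
  expect_equal(attr(d1, "ddct"), 3)
  expect_equal(attr(d1, "rq"), 0.125)
  # equal shifts in target and reference cancel
  d2 <- ddct(c(20, 20, 22, 22), c(15, 15, 17, 17), c("CK", "CK", "LT", "LT"))
  expect_equal(attr(d2, "rq"), 1)
  expect_error(ddct(1:3, 1:2, c("a", "b")), "matching")
  expect_equal(glance(d1)$rq, 0.125)
})
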