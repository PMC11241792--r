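# Shared fixture builders. Everything is generated in code; no data files.

# Offset table holding a simulation config's true offsets, for localizing
# P-sites independently of the offset estimator.
true_offset_table <- function(config) {
  tibble::tibble(
    length = as.integer(names(config$true_offsets)),
    offset = as.integer(config$true_offsets),
    n_support = NA_integer_,
    flag = "estimated"
  )
}

# A condition-invariant per-codon dwell landscape (lognormal multipliers at
# E/P/A) emulating real codon-to-codon decoding-speed variation.
dwell_landscape <- function(seed, sdlog = 0.3) {
  sense <- setdiff(all_codons("rna"), c("UAA", "UAG", "UGA"))
  withr::with_seed(seed, {
    lapply(c(E = "E", P = "P", A = "A"), function(s) {
      stats::setNames(stats::rlnorm(length(sense), 0, sdlog), sense)
    })
  })
}

# Deterministic two-transcript toy annotation used by the I/O tests.
toy_transcripts <- function() {
  transcript_models(
    transcript_id = c("t1", "t2"),
    sequence = c(
      paste0("ACGTAC", "ATGAAACCCGGGTAA", "TTTACGTTT"),       # 6 / 15 / 9
      paste0(strrep("A", 10), "ATGCATCATTGA", strrep("C", 8)) # 10 / 12 / 8
    ),
    cds_start = c(6, 10),
    cds_end = c(21, 22)
  )
}

# Minimal alignment tibble constructor.
aln_tbl <- function(transcript_id, five_prime, length, library_id = "lib1") {
  tibble::tibble(
    transcript_id = transcript_id,
    five_prime = as.integer(five_prime),
    length = as.integer(length),
    library_id = library_id
  )
}
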