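# P-site calibration: read-length spectrum, per-length offset estimation
# from start-codon metagene profiles, and conversion of raw alignments into
# localized P-site records with frame, region and E/P/A codons.

#' Footprint length histogram
#'
#' @param alignments alignment tibble.
#' @param keep_range inclusive read-length window retained for analysis
#'   (wider than the canonical 28--31 nt so the reported range is an
#'   observation, not an input).
#' @return Tibble `length`, `count` with attributes `modal_length` (smallest
#'   length achieving the maximum count) and `n_dropped`.
#' @export
length_histogram <- function(alignments, keep_range = c(25, 34)) {
  keep <- alignments$length >= keep_range[1L] &
    alignments$length <= keep_range[2L]
  n_dropped <- sum(!keep)
  if (!any(keep)) {
    abort("all reads fall outside keep_range; widen the length window")
  }
  hist <- alignments[keep, ] %>%
    count(.data$length, name = "count") %>%
    arrange(.data$length)
  modal <- hist$length[hist$count == max(hist$count)][1L]
  structure(hist, modal_length = modal, n_dropped = n_dropped)
}

#' Estimate per-read-length P-site offsets from the start-codon profile
#'
#' For each read length L, the distances `d = cds_start - five_prime` of
#' reads whose 5' end lies within `flank` nt upstream of a start codon are
#' histogrammed over `search_range` (intersected with `[6, L - 6]`). The raw
#' offset is the smallest d maximizing that histogram; it is then frame-
#' corrected by choosing, among `raw - 1, raw, raw + 1`, the candidate that
#' maximizes the genome-wide frame-0 fraction of CDS P-sites (ties to the
#' smaller offset). Lengths with fewer than `min_support` supporting reads
#' fall back to the modal length's offset.
#'
#' @param alignments length-filtered alignment tibble.
#' @param transcripts transcript models.
#' @param flank upstream window (nt) around start codons.
#' @param min_support minimum supporting reads for a per-length estimate.
#' @param search_range inclusive candidate-offset interval.
#' @return Tibble `length`, `offset`, `n_support`, `flag`
#'   (`estimated`/`fallback`) with attribute `profiles` (per-length distance
#'   histograms). Class `ribo_offsets`.
#' @export
estimate_offsets <- function(alignments, transcripts, flank = 30,
                             min_support = 50, search_range = c(6, 18)) {
  if (search_range[1L] > search_range[2L]) abort("empty search_range")
  assert_columns(alignments, c("transcript_id", "five_prime", "length"),
                 "alignments")
  aln <- alignments %>%
    inner_join(transcripts[, c("transcript_id", "cds_start", "cds_end")],
               by = "transcript_id")
  if (!nrow(aln)) abort("no alignments on annotated transcripts")
  lengths <- sort(unique(aln$length))
  profiles <- list()
  rows <- lapply(lengths, function(L) {
    sub <- aln[aln$length == L, ]
    d <- sub$cds_start - sub$five_prime
    lo <- max(search_range[1L], 6L)
    hi <- min(search_range[2L], L - 6L)
    d <- d[d >= 1L & d <= flank]
    d <- d[d >= lo & d <= hi]
    profiles[[as.character(L)]] <<- tibble(distance = seq.int(lo, hi)) %>%
      left_join(tibble(distance = d) %>% count(.data$distance, name = "count"),
                by = "distance") %>%
      tidyr::replace_na(list(count = 0L))
    n_support <- length(d)
    if (n_support < min_support || lo > hi) {
      return(tibble(length = L, offset = NA_integer_,
                    n_support = n_support, flag = "fallback"))
    }
    tab <- table(d)
    raw <- as.integer(names(tab)[which.max(tab)])  # smallest maximizer
    cands <- intersect((raw - 1L):(raw + 1L), lo:hi)
    f0 <- vapply(cands, function(cand) {
      ps <- sub$five_prime + cand
      in_cds <- ps >= sub$cds_start & ps < sub$cds_end
      if (!any(in_cds)) return(0)
      mean((ps[in_cds] - sub$cds_start[in_cds]) %% 3L == 0L)
    }, numeric(1))
    best <- cands[f0 == max(f0)][1L]
    tibble(length = L, offset = as.integer(best),
           n_support = n_support, flag = "estimated")
  })
  out <- bind_rows(rows)
  hist <- length_histogram(aln, keep_range = range(lengths))
  modal <- attr(hist, "modal_length")
  modal_row <- out[out$length == modal, ]
  if (nrow(modal_row) == 0L || modal_row$flag != "estimated") {
    abort(sprintf(
      "modal read length (%d nt) lacks support for offset estimation", modal))
  }
  out$offset[out$flag == "fallback"] <- modal_row$offset
  structure(out, profiles = profiles, modal_length = modal,
            class = c("ribo_offsets", class(out)))
}

#' Convert alignments to localized P-site records
#'
#' `psite_pos = five_prime + offset[length]`. Records whose P-site codon
#' extends past either transcript end are dropped and counted. Frame is
#' `(psite_pos - cds_start) mod 3`, defined only inside the CDS. E/P/A
#' codons are reported in RNA spelling; E (P-site - 3 nt) and A (+3 nt)
#' codons are `NA` when out of transcript bounds.
#'
#' @param alignments alignment tibble.
#' @param offsets offset table from [estimate_offsets()] (or a tibble
#'   `length`, `offset`).
#' @param transcripts transcript models.
#' @return Tibble `transcript_id`, `psite_pos`, `read_length`, `frame`,
#'   `region`, `codon_E`, `codon_P`, `codon_A`, `library_id`, with attribute
#'   `n_dropped`.
#' @export
localize_psites <- function(alignments, offsets, transcripts) {
  if ("flag" %in% names(offsets) && any(offsets$flag == "excluded")) {
    excl <- offsets$length[offsets$flag == "excluded"]
    n_excl <- sum(alignments$length %in% excl)
    if (n_excl > 0L) {
      warn(sprintf("%d read(s) with excluded lengths dropped", n_excl))
    }
    alignments <- alignments[!alignments$length %in% excl, ]
    offsets <- offsets[offsets$flag != "excluded", ]
  }
  missing_len <- setdiff(unique(alignments$length), offsets$length)
  if (length(missing_len)) {
    abort(sprintf("no offset for read length(s): %s",
                  paste(missing_len, collapse = ", ")))
  }
  aln <- alignments %>%
    mutate(offset = offsets$offset[match(.data$length, offsets$length)]) %>%
    inner_join(transcripts[, c("transcript_id", "sequence", "cds_start",
                               "cds_end", "length")],
               by = "transcript_id", suffix = c("", "_tx"))
  psite_pos <- aln$five_prime + aln$offset
  keep <- psite_pos >= 0L & psite_pos + 3L <= aln$length_tx
  n_dropped <- sum(!keep)
  aln <- aln[keep, ]
  psite_pos <- psite_pos[keep]
  region <- region_of(psite_pos, aln$cds_start, aln$cds_end)
  frame <- ifelse(region == "cds", (psite_pos - aln$cds_start) %% 3L,
                  NA_integer_)
  codon_at <- function(start0) {
    ok <- start0 >= 0L & start0 + 3L <= aln$length_tx
    out <- rep(NA_character_, length(start0))
    out[ok] <- to_rna(substr(aln$sequence[ok], start0[ok] + 1L,
                             start0[ok] + 3L))
    out
  }
  out <- tibble(
    transcript_id = aln$transcript_id,
    psite_pos = as.integer(psite_pos),
    read_length = aln$length,
    frame = as.integer(frame),
    region = region,
    codon_E = codon_at(psite_pos - 3L),
    codon_P = codon_at(psite_pos),
    codon_A = codon_at(psite_pos + 3L),
    library_id = aln$library_id
  )
  structure(out, n_dropped = n_dropped)
}

#' Write an offset table as TSV (and optionally JSON)
#'
#' @param offsets offset table.
#' @param path TSV output path.
#' @param json_path optional JSON output path for machine reuse.
#' @export
write_offsets <- function(offsets, path, json_path = NULL) {
  readr::write_tsv(as_tibble(offsets), path, progress = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      setNames(as.list(offsets$offset), offsets$length),
      json_path, auto_unbox = TRUE
    )
  }
  invisible(path)
}
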