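# Transcript models, alignment I/O and counting.
#
# Coordinates are 0-based, half-open throughout: a CDS occupies
# [cds_start, cds_end) on the transcript, and an aligned footprint covers
# [five_prime, five_prime + length). SAM (1-based) is converted at the
# boundary.

#' Build and validate a table of transcript models
#'
#' A transcript model is the coding-strand sequence of a transcript plus its
#' CDS boundaries, which define the 5'UTR / CDS / 3'UTR geometry used by all
#' downstream stages.
#'
#' @param transcript_id character vector of unique identifiers.
#' @param sequence nucleotide sequences over A/C/G/T (U is accepted and
#'   mapped to T; case-insensitive).
#' @param cds_start,cds_end integer CDS boundaries, 0-based half-open.
#' @return A tibble with one row per transcript and columns `transcript_id`,
#'   `sequence`, `cds_start`, `cds_end`, `length`, `utr5_len`, `cds_len`,
#'   `utr3_len`.
#' @export
transcript_models <- function(transcript_id, sequence, cds_start, cds_end) {
  sequence <- to_dna(toupper(sequence))
  tbl <- tibble(
    transcript_id = as.character(transcript_id),
    sequence = sequence,
    cds_start = as.integer(cds_start),
    cds_end = as.integer(cds_end),
    length = nchar(sequence)
  )
  if (anyDuplicated(tbl$transcript_id)) {
    abort("duplicated transcript_id in transcript models")
  }
  bad_alpha <- grepl("[^ACGT]", tbl$sequence)
  if (any(bad_alpha)) {
    abort(sprintf("non-ACGTU characters in sequence of: %s",
                  paste(tbl$transcript_id[bad_alpha], collapse = ", ")))
  }
  bad <- with(tbl, !(cds_start >= 0 & cds_start < cds_end & cds_end <= length))
  if (any(bad)) {
    abort(sprintf("CDS outside sequence bounds for: %s",
                  paste(tbl$transcript_id[bad], collapse = ", ")))
  }
  cds_len <- tbl$cds_end - tbl$cds_start
  bad <- cds_len %% 3L != 0L | cds_len < 6L
  if (any(bad)) {
    abort(sprintf("CDS length must be a multiple of 3 and >= 6 for: %s",
                  paste(tbl$transcript_id[bad], collapse = ", ")))
  }
  tbl %>%
    mutate(
      utr5_len = .data$cds_start,
      cds_len = .data$cds_end - .data$cds_start,
      utr3_len = .data$length - .data$cds_end
    )
}

#' Read transcript models from FASTA plus a CDS annotation TSV
#'
#' @param fasta_path FASTA of transcript sequences.
#' @param annotation_path TSV with header `transcript_id`, `cds_start`,
#'   `cds_end` (0-based half-open).
#' @return A transcript-model tibble (see [transcript_models()]). Records
#'   present in only one of the two files are reported and skipped.
#' @export
read_transcripts <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  ann <- readr::read_tsv(annotation_path, show_col_types = FALSE,
                         progress = FALSE)
  assert_columns(ann, c("transcript_id", "cds_start", "cds_end"),
                 "annotation TSV")
  ann$transcript_id <- as.character(ann$transcript_id)
  only_fa <- setdiff(ids, ann$transcript_id)
  only_ann <- setdiff(ann$transcript_id, ids)
  if (length(only_fa)) {
    warn(sprintf("%d FASTA record(s) without annotation skipped (e.g. %s)",
                 length(only_fa), only_fa[[1L]]))
  }
  if (length(only_ann)) {
    warn(sprintf("%d annotation row(s) without sequence skipped (e.g. %s)",
                 length(only_ann), only_ann[[1L]]))
  }
  shared <- intersect(ids, ann$transcript_id)
  if (!length(shared)) abort("no transcript shared between FASTA and annotation")
  ann <- ann[match(shared, ann$transcript_id), ]
  transcript_models(
    transcript_id = shared,
    sequence = as.character(seqs[match(shared, ids)]),
    cds_start = ann$cds_start,
    cds_end = ann$cds_end
  )
}

#' Write transcript models to FASTA + annotation TSV
#'
#' @param transcripts transcript-model tibble.
#' @param fasta_path,annotation_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_transcripts <- function(transcripts, fasta_path, annotation_path) {
  set <- Biostrings::DNAStringSet(setNames(transcripts$sequence,
                                           transcripts$transcript_id))
  Biostrings::writeXStringSet(set, fasta_path, width = 70L)
  readr::write_tsv(
    transcripts[, c("transcript_id", "cds_start", "cds_end")],
    annotation_path, progress = FALSE
  )
  invisible(c(fasta_path, annotation_path))
}

#' Read footprint alignments in transcript coordinates
#'
#' Two dialects are supported: a plain TSV (`transcript_id`, `five_prime`,
#' `length`, optional `library_id`) and SAM/BAM with transcript references.
#' For SAM/BAM, unmapped, secondary and supplementary records are excluded
#' and 1-based POS is converted to the 0-based `five_prime`.
#'
#' @param path input file.
#' @param dialect `"auto"` (by extension), `"tsv"`, or `"sam_bam"`.
#' @param library_id library tag attached to the reads when the file carries
#'   none.
#' @param transcripts optional transcript models; records aligned to unknown
#'   references are dropped and counted (error only if all records drop).
#' @return Tibble `transcript_id`, `five_prime`, `length`, `library_id`, with
#'   attributes `n_dropped_flag` (SAM filters) and `n_dropped_reference`.
#' @export
read_alignments <- function(path, dialect = c("auto", "tsv", "sam_bam"),
                            library_id = NULL, transcripts = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE))
      "sam_bam" else "tsv"
  }
  if (dialect == "tsv") {
    aln <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (nrow(aln) == 0L) {
      warn(sprintf("no alignments in %s", path))
      aln <- tibble(transcript_id = character(), five_prime = integer(),
                    length = integer())
    }
    assert_columns(aln, c("transcript_id", "five_prime", "length"),
                   "alignment TSV")
    n_flag_dropped <- 0L
  } else {
    bam <- path
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
      bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                              indexDestination = FALSE)
    }
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    param <- Rsamtools::ScanBamParam(flag = flag,
                                     what = c("rname", "pos", "qwidth"))
    rec <- Rsamtools::scanBam(bam, param = param)[[1L]]
    total <- Rsamtools::countBam(bam)$records
    n_flag_dropped <- total - length(rec$pos)
    aln <- tibble(
      transcript_id = as.character(rec$rname),
      five_prime = as.integer(rec$pos) - 1L,
      length = as.integer(rec$qwidth)
    )
  }
  aln$transcript_id <- as.character(aln$transcript_id)
  aln$five_prime <- as.integer(aln$five_prime)
  aln$length <- as.integer(aln$length)
  if (!"library_id" %in% names(aln)) {
    aln$library_id <- library_id %||%
      sub("\\.(tsv|sam|bam)$", "", basename(path), ignore.case = TRUE)
  }
  n_ref_dropped <- 0L
  if (!is.null(transcripts)) {
    known <- aln$transcript_id %in% transcripts$transcript_id
    n_ref_dropped <- sum(!known)
    if (nrow(aln) > 0L && n_ref_dropped == nrow(aln)) {
      abort(sprintf("all %d alignment(s) in %s reference unknown transcripts",
                    n_ref_dropped, path))
    }
    aln <- aln[known, ]
  }
  inform(sprintf("read %d alignment(s) from %s (%d dropped by flag, %d by reference)",
                 nrow(aln), basename(path), n_flag_dropped, n_ref_dropped))
  structure(as_tibble(aln),
            n_dropped_flag = n_flag_dropped,
            n_dropped_reference = n_ref_dropped)
}

#' Write alignments in the TSV dialect
#'
#' @param alignments alignment tibble.
#' @param path output path.
#' @export
write_alignments <- function(alignments, path) {
  readr::write_tsv(
    alignments[, c("transcript_id", "five_prime", "length", "library_id")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Count alignments per transcript and library
#'
#' @param alignments alignment tibble (possibly several libraries).
#' @param transcripts transcript models; every annotated transcript gets a
#'   row, zero counts included.
#' @param region_filter `"all"` keeps every alignment; `"cds_only"` keeps
#'   alignments whose P-site (when `offsets` is given) or 5' end falls inside
#'   the CDS.
#' @param offsets optional offset table from [estimate_offsets()] used to
#'   place P-sites for the CDS filter.
#' @return A wide count tibble: `transcript_id` plus one non-negative integer
#'   column per library.
#' @export
count_by_transcript <- function(alignments, transcripts,
                                region_filter = c("all", "cds_only"),
                                offsets = NULL) {
  region_filter <- match.arg(region_filter)
  assert_columns(alignments, c("transcript_id", "five_prime", "length",
                               "library_id"), "alignments")
  unknown <- setdiff(unique(alignments$transcript_id),
                     transcripts$transcript_id)
  if (length(unknown)) {
    abort(sprintf("alignments reference unknown transcript(s): %s",
                  paste(head(unknown, 3L), collapse = ", ")))
  }
  aln <- alignments
  if (region_filter == "cds_only") {
    pos <- aln$five_prime
    if (!is.null(offsets)) {
      off <- offsets$offset[match(aln$length, offsets$length)]
      pos <- ifelse(is.na(off), pos, pos + off)
    }
    bounds <- transcripts[match(aln$transcript_id,
                                transcripts$transcript_id), ]
    aln <- aln[pos >= bounds$cds_start & pos < bounds$cds_end, ]
  }
  libs <- sort(unique(alignments$library_id))
  wide <- aln %>%
    count(.data$transcript_id, .data$library_id) %>%
    tidyr::pivot_wider(names_from = "library_id", values_from = "n",
                       values_fill = 0L)
  out <- tibble(transcript_id = transcripts$transcript_id) %>%
    left_join(wide, by = "transcript_id")
  for (lib in libs) {
    if (!lib %in% names(out)) out[[lib]] <- 0L
    out[[lib]][is.na(out[[lib]])] <- 0L
    out[[lib]] <- as.integer(out[[lib]])
  }
  out[, c("transcript_id", libs)]
}

# Internal: counts tibble -> integer matrix with transcript_id rownames.
count_matrix <- function(counts) {
  m <- as.matrix(counts[, setdiff(names(counts), "transcript_id")])
  storage.mode(m) <- "double"
  rownames(m) <- counts$transcript_id
  m
}
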