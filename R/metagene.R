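# Metagene profiles, 3-nt periodicity diagnostics, per-length P-site
# heatmaps, and observed-versus-expected P-site distribution across
# 5'UTR / CDS / 3'UTR.

# Position of each P-site relative to an anchor: start = first nt of the
# start codon; stop = first nt of the stop codon.
anchor_positions <- function(psites, transcripts, anchor) {
  tx <- transcripts[match(psites$transcript_id, transcripts$transcript_id), ]
  if (anchor == "start") psites$psite_pos - tx$cds_start
  else psites$psite_pos - (tx$cds_end - 3L)
}

#' Metagene profile of P-site signal around the start or stop codon
#'
#' With `normalization = "per_transcript_mean"` each transcript's window
#' counts are divided by that transcript's mean CDS P-site density (CDS
#' P-sites per CDS nt) before summation, so a few highly expressed
#' transcripts cannot dominate the profile; transcripts with zero CDS
#' density are excluded. `"raw"` sums counts.
#'
#' @param psites P-site records from [localize_psites()].
#' @param transcripts transcript models.
#' @param anchor `"start"` or `"stop"` (position 0 = first nt of the anchor
#'   codon).
#' @param window inclusive position window relative to the anchor, nt.
#' @param normalization `"per_transcript_mean"` or `"raw"`.
#' @return Tibble `position`, `value` covering the window exactly, with
#'   attributes `anchor`, `normalization`, `n_transcripts`.
#' @export
metagene_profile <- function(psites, transcripts,
                             anchor = c("start", "stop"),
                             window = c(-30, 60),
                             normalization = c("per_transcript_mean",
                                               "raw")) {
  anchor <- match.arg(anchor)
  normalization <- match.arg(normalization)
  if (!nrow(psites)) abort("empty P-site set")
  rel <- anchor_positions(psites, transcripts, anchor)
  grid <- tibble(position = seq.int(window[1L], window[2L]))
  in_win <- rel >= window[1L] & rel <= window[2L]
  df <- tibble(transcript_id = psites$transcript_id[in_win],
               position = rel[in_win])
  if (normalization == "raw") {
    prof <- df %>% count(.data$position, name = "value")
    n_tx <- dplyr::n_distinct(df$transcript_id)
  } else {
    dens <- psites %>%
      filter(.data$region == "cds") %>%
      count(.data$transcript_id, name = "n_cds") %>%
      inner_join(transcripts[, c("transcript_id", "cds_len")],
                 by = "transcript_id") %>%
      mutate(weight = .data$cds_len / .data$n_cds)
    df <- df %>% inner_join(dens[, c("transcript_id", "weight")],
                            by = "transcript_id")
    prof <- df %>%
      group_by(.data$position) %>%
      summarise(value = sum(.data$weight), .groups = "drop")
    n_tx <- nrow(dens)
  }
  out <- grid %>%
    left_join(prof, by = "position") %>%
    tidyr::replace_na(list(value = 0))
  structure(out, anchor = anchor, normalization = normalization,
            n_transcripts = n_tx)
}

#' Per-library reading-frame fractions of CDS P-sites
#'
#' The fraction of CDS P-sites in frames 0/1/2 is the package's 3-nt
#' periodicity summary; a frame-0 fraction well above 1/3 is the classic
#' signature of elongating ribosomes.
#'
#' @param psites P-site records.
#' @return Tibble `library_id`, `n`, `f0`, `f1`, `f2` (fractions sum to 1).
#' @export
frame_fractions <- function(psites) {
  cds <- psites %>% filter(.data$region == "cds")
  if (!nrow(cds)) abort("no CDS P-sites")
  cds %>%
    group_by(.data$library_id) %>%
    summarise(n = n(),
              f0 = mean(.data$frame == 0L),
              f1 = mean(.data$frame == 1L),
              f2 = mean(.data$frame == 2L),
              .groups = "drop")
}

#' P-site heatmap by read length around an anchor
#'
#' @param psites P-site records.
#' @param transcripts transcript models.
#' @param anchor,window as in [metagene_profile()].
#' @return Long tibble `read_length`, `position`, `count` (full grid, zeros
#'   filled), attribute `anchor`. Summing rows over lengths reproduces the
#'   raw metagene profile on the same window.
#' @export
periodicity_heatmap <- function(psites, transcripts,
                                anchor = c("start", "stop"),
                                window = c(-30, 60)) {
  anchor <- match.arg(anchor)
  if (!nrow(psites)) abort("empty P-site set")
  rel <- anchor_positions(psites, transcripts, anchor)
  in_win <- rel >= window[1L] & rel <= window[2L]
  df <- tibble(read_length = psites$read_length[in_win],
               position = rel[in_win]) %>%
    count(.data$read_length, .data$position, name = "count")
  grid <- tidyr::expand_grid(
    read_length = sort(unique(psites$read_length)),
    position = seq.int(window[1L], window[2L])
  )
  out <- grid %>%
    left_join(df, by = c("read_length", "position")) %>%
    tidyr::replace_na(list(count = 0L))
  structure(out, anchor = anchor)
}

#' Observed vs expected P-site distribution across 5'UTR / CDS / 3'UTR
#'
#' Observed fractions are the per-region shares of P-sites. The expected
#' ("random positioning") model is each region's total length over the
#' detected transcripts (those with at least one P-site) divided by their
#' total transcript length, i.e. what uniformly scattered signal on the
#' measured transcript population would give.
#'
#' @param psites P-site records.
#' @param transcripts transcript models.
#' @return Tibble `region`, `n_psites`, `region_length`, `observed`,
#'   `expected`; both fraction columns sum to 1.
#' @export
region_distribution <- function(psites, transcripts) {
  if (!nrow(psites)) abort("no detected transcripts: empty P-site set")
  detected <- transcripts %>%
    filter(.data$transcript_id %in% unique(psites$transcript_id))
  lens <- c(utr5 = sum(detected$utr5_len), cds = sum(detected$cds_len),
            utr3 = sum(detected$utr3_len))
  obs <- table(factor(psites$region, levels = REGIONS))
  tibble(
    region = REGIONS,
    n_psites = as.integer(obs),
    region_length = as.numeric(lens),
    observed = as.numeric(obs) / sum(obs),
    expected = as.numeric(lens) / sum(lens)
  )
}
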