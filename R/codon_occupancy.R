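# Genome-wide codon usage, site-resolved (E/P/A) codon-occupancy indices,
# ranking tables, and cross-condition comparison with outlier-codon
# detection. The occupancy index of a codon at a site is its share of
# site-resolved P-site-anchored signal divided by its genome-wide usage
# frequency; values > 1 suggest slow decoding / stalling.

#' Genome-wide codon usage over coding sequences
#'
#' Counts every in-frame codon (start and stop included) of each CDS and
#' normalizes to frequencies. Duplicated transcripts count twice: usage is a
#' codon tally, not a per-gene average.
#'
#' @param transcripts transcript models.
#' @param psites optional P-site records; with `scope = "detected"` usage is
#'   computed over transcripts carrying at least one P-site, so the
#'   reference population matches the measured one.
#' @param scope `"detected"` (requires `psites`) or `"all"`.
#' @param site optional availability matching: with `"E"`/`"P"`/`"A"` the
#'   tally is restricted to CDS codon positions that a P-site inside the CDS
#'   can actually place in that site (the first codon of a CDS can never
#'   occupy the A site, nor the last the E site), which removes a structural
#'   bias of occupancy indices at start/stop-adjacent codons.
#' @return Tibble with all 64 codons (RNA spelling): `codon`, `count`,
#'   `frequency`, `is_stop`.
#' @export
codon_usage <- function(transcripts, psites = NULL,
                        scope = c("detected", "all"), site = NULL) {
  scope <- match.arg(scope)
  if (scope == "detected") {
    if (is.null(psites)) abort("scope = 'detected' requires psites")
    transcripts <- transcripts %>%
      filter(.data$transcript_id %in% unique(psites$transcript_id))
    if (!nrow(transcripts)) abort("no detected transcripts")
  }
  cds_seq <- substr(transcripts$sequence, transcripts$cds_start + 1L,
                    transcripts$cds_end)
  codon_list <- lapply(cds_seq, split_codons)
  if (!is.null(site)) {
    site <- match.arg(site, c("E", "P", "A"))
    codon_list <- lapply(codon_list, function(x) {
      if (site == "A") x[-1L] else if (site == "E") x[-length(x)] else x
    })
  }
  codons <- to_rna(unlist(codon_list, use.names = FALSE))
  tab <- table(factor(codons, levels = all_codons("rna")))
  tibble(
    codon = all_codons("rna"),
    count = as.integer(tab),
    frequency = as.numeric(tab) / sum(tab),
    is_stop = is_stop_codon(all_codons("rna"))
  )
}

#' Site-resolved codon counts from CDS P-sites
#'
#' Uses P-site records localized inside the CDS whose site codon (E = P-site
#' codon - 3 nt, A = + 3 nt) lies fully within the CDS; site codons
#' extending into a UTR are excluded.
#'
#' @param psites P-site records.
#' @param transcripts transcript models (for CDS bounds).
#' @param site `"E"`, `"P"` or `"A"`.
#' @return Tibble `codon` (all 64, RNA spelling), `count`.
#' @export
site_codon_counts <- function(psites, transcripts, site = c("P", "E", "A")) {
  site <- match.arg(site)
  if (!nrow(psites)) abort("empty P-site set")
  shift <- c(E = -3L, P = 0L, A = 3L)[[site]]
  tx <- transcripts[match(psites$transcript_id, transcripts$transcript_id), ]
  s0 <- psites$psite_pos + shift
  keep <- psites$region == "cds" & s0 >= tx$cds_start & s0 + 3L <= tx$cds_end
  codon <- psites[[paste0("codon_", site)]][keep]
  codon <- codon[!is.na(codon)]
  if (!length(codon)) abort(sprintf("no usable %s-site codons", site))
  tab <- table(factor(codon, levels = all_codons("rna")))
  tibble(codon = all_codons("rna"), count = as.integer(tab))
}

#' Codon occupancy index table for one site and library group
#'
#' `index(c) = (count(c) / total counts) / usage_frequency(c)`. Codons with
#' zero usage frequency are flagged undefined (no pseudocount smoothing) and
#' excluded from the ranking; ranks are by descending index, ties broken
#' alphabetically.
#'
#' @param counts per-codon counts from [site_codon_counts()].
#' @param usage codon usage from [codon_usage()].
#' @param site,group labels stored on the table.
#' @return Tibble `codon`, `count`, `occupancy`, `usage`, `index`,
#'   `defined`, `is_stop`, `rank`; class `ribo_codon_index` with attributes
#'   `site` and `group`.
#' @export
codon_index <- function(counts, usage, site = NA_character_,
                        group = NA_character_) {
  total <- sum(counts$count)
  if (total == 0L) abort("site codon counts sum to zero")
  tbl <- counts %>%
    left_join(usage[, c("codon", "frequency", "is_stop")], by = "codon") %>%
    mutate(
      occupancy = .data$count / total,
      usage = .data$frequency,
      defined = .data$usage > 0,
      index = if_else(.data$defined, .data$occupancy / .data$usage,
                      NA_real_)
    ) %>%
    select("codon", "count", "occupancy", "usage", "index", "defined",
           "is_stop")
  ranked <- tbl %>%
    filter(.data$defined) %>%
    arrange(desc(.data$index), .data$codon) %>%
    mutate(rank = row_number())
  tbl <- tbl %>%
    left_join(ranked[, c("codon", "rank")], by = "codon")
  structure(tbl, site = site, group = group,
            class = c("ribo_codon_index", class(tbl)))
}

#' One-call occupancy index from P-sites
#'
#' @param psites P-site records (pool the libraries of one group before
#'   calling, or filter per library).
#' @param transcripts transcript models.
#' @param site `"E"`, `"P"` or `"A"`.
#' @param usage optional precomputed usage; by default the availability-
#'   matched usage of the detected transcripts for this site (see
#'   [codon_usage()]).
#' @param group label stored on the table.
#' @return See [codon_index()].
#' @export
occupancy_index <- function(psites, transcripts, site, usage = NULL,
                            group = NA_character_) {
  usage <- usage %||%
    codon_usage(transcripts, psites, scope = "detected", site = site)
  codon_index(site_codon_counts(psites, transcripts, site), usage,
              site = site, group = group)
}

#' Compare codon occupancy between two groups and flag outlier codons
#'
#' Pearson correlation over paired defined indices, per-codon log2 index
#' ratios (group 2 over group 1), and a robust z-score
#' `z = (log2 ratio - median) / (1.4826 * MAD)`. Codons with
#' `|z| >= z_threshold` are flagged as outliers with their direction; stop
#' codons are kept in the table but excluded from the outlier statistics by
#' default (they are reported with an asterisk convention downstream).
#'
#' @param table1,table2 [codon_index()] tables for the same site.
#' @param z_threshold robust z cut for outlier codons.
#' @param exclude_stops exclude stop codons from median/MAD and outlier
#'   flags.
#' @return Tibble `codon`, `is_stop`, `index_1`, `index_2`, `log2_ratio`,
#'   `z`, `outlier`, `direction`; class `ribo_occupancy_comparison` with
#'   attributes `pearson_r`, `site`, `groups`, `z_threshold`.
#' @export
compare_occupancy <- function(table1, table2, z_threshold = 2.5,
                              exclude_stops = TRUE) {
  s1 <- attr(table1, "site"); s2 <- attr(table2, "site")
  if (!is.na(s1) && !is.na(s2) && !identical(s1, s2)) {
    abort("occupancy tables are for different sites")
  }
  j <- inner_join(
    table1[, c("codon", "is_stop", "index", "defined")],
    table2[, c("codon", "index", "defined")],
    by = "codon", suffix = c("_1", "_2")
  ) %>%
    filter(.data$defined_1 & .data$defined_2) %>%
    select("codon", "is_stop", index_1 = "index_1", index_2 = "index_2")
  if (nrow(j) < 10L) {
    abort("fewer than 10 shared defined codons; correlation is meaningless")
  }
  r <- cor(j$index_1, j$index_2, method = "pearson")
  j <- j %>%
    mutate(log2_ratio = log2(.data$index_2 / .data$index_1))
  usable <- is.finite(j$log2_ratio) & (!exclude_stops | !j$is_stop)
  med <- median(j$log2_ratio[usable])
  s <- 1.4826 * mad(j$log2_ratio[usable], constant = 1)
  j <- j %>%
    mutate(
      z = dplyr::case_when(
        is.finite(.data$log2_ratio) & s > 0 ~ (.data$log2_ratio - med) / s,
        is.finite(.data$log2_ratio) & .data$log2_ratio == med ~ 0,
        TRUE ~ NA_real_
      ),
      outlier = !is.na(.data$z) & abs(.data$z) >= z_threshold &
        (!exclude_stops | !.data$is_stop),
      direction = dplyr::case_when(
        .data$outlier & .data$z > 0 ~ "up",
        .data$outlier & .data$z < 0 ~ "down",
        TRUE ~ "ns"
      )
    )
  structure(j, pearson_r = r, site = s1 %||% s2,
            groups = c(attr(table1, "group"), attr(table2, "group")),
            z_threshold = z_threshold,
            class = c("ribo_occupancy_comparison", class(j)))
}
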