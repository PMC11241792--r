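# End-to-end orchestration: a validated config drives simulate (optional) ->
# P-site calibration -> metagene -> codon occupancy -> expression, writing
# stage TSVs and a consolidated JSON + Markdown report. All randomness flows
# from the single config seed, so a rerun with the same config is
# byte-identical.

PIPELINE_KEYS <- c(
  "fasta", "annotation", "alignments", "metadata", "out_dir", "simulate",
  "sim", "keep_range", "flank", "min_support", "search_range", "window",
  "z_threshold", "alpha", "lfc", "conditions", "seed"
)

#' Build and validate a pipeline configuration
#'
#' Either point `fasta`/`annotation`/`alignments`/`metadata` at files, or
#' set `simulate = TRUE` (with optional [sim_config()] arguments in `sim`)
#' to run on generated data. Unknown keys are rejected.
#'
#' @param ... configuration entries; see `riboscope:::PIPELINE_KEYS`.
#' @return Validated config list of class `ribo_pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) == 1L && is.null(names(cfg)) && is.character(cfg[[1L]])) {
    cfg <- yaml::read_yaml(cfg[[1L]])
  }
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  defaults <- list(
    simulate = FALSE, keep_range = c(25, 34), flank = 30, min_support = 50,
    search_range = c(6, 18), window = c(-30, 60), z_threshold = 2.5,
    alpha = 0.05, lfc = 1, conditions = NULL, seed = 1
  )
  cfg <- modifyList(defaults, cfg)
  if (!isTRUE(cfg$simulate)) {
    for (key in c("fasta", "annotation", "metadata")) {
      if (is.null(cfg[[key]])) abort(sprintf("config key '%s' is required", key))
      if (!file.exists(cfg[[key]])) {
        abort(sprintf("config path '%s' does not exist: %s", key, cfg[[key]]))
      }
    }
    if (is.null(cfg$alignments)) abort("config key 'alignments' is required")
    missing <- cfg$alignments[!file.exists(unlist(cfg$alignments))]
    if (length(missing)) {
      abort(sprintf("alignment file(s) missing: %s",
                    paste(unlist(missing), collapse = ", ")))
    }
  }
  structure(cfg, class = "ribo_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (optional) simulation; P-site offset calibration and
#' localization; metagene/periodicity/region diagnostics; per-site codon
#' occupancy with cross-condition comparison; differential expression at
#' both levels plus translation efficiency. Each stage's table is written as
#' TSV under `out_dir`, and a consolidated `report.json` / `report.md` pair
#' summarizes the run. Every number in the report is recomputable from the
#' emitted TSVs.
#'
#' @param config a [pipeline_config()] (or arguments for one).
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return The report (named list), invisibly; also written as JSON.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "ribo_pipeline_config")) {
    config <- do.call(pipeline_config, as.list(config))
  }
  out_dir <- out_dir %||% config$out_dir %||% abort("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  stage <- "input"
  on.exit({
    if (!is.null(stage)) {
      writeLines(stage, p("FAILED"))
    }
  }, add = TRUE)

  if (isTRUE(config$simulate)) {
    sim_args <- config$sim %||% list()
    sim_args$seed <- sim_args$seed %||% config$seed
    scfg <- do.call(sim_config, sim_args)
    dataset <- simulate_dataset(scfg)
    write_dataset(dataset, p("simulated"))
    transcripts <- dataset$transcripts
    alignments <- dataset$alignments
    meta <- dataset$meta
  } else {
    transcripts <- read_transcripts(config$fasta, config$annotation)
    meta <- readr::read_tsv(config$metadata, show_col_types = FALSE,
                            progress = FALSE)
    alignments <- bind_rows(lapply(unlist(config$alignments), function(f) {
      read_alignments(f, transcripts = transcripts)
    }))
  }
  rpf_libs <- meta$library_id[meta$assay == "RPF"]
  rpf <- alignments %>% filter(.data$library_id %in% rpf_libs)

  stage <- "psite"
  hist <- length_histogram(rpf, keep_range = config$keep_range)
  readr::write_tsv(as_tibble(hist), p("length_histogram.tsv"),
                   progress = FALSE)
  kept <- rpf %>% filter(.data$length >= config$keep_range[1L],
                         .data$length <= config$keep_range[2L])
  offsets <- estimate_offsets(kept, transcripts, flank = config$flank,
                              min_support = config$min_support,
                              search_range = config$search_range)
  write_offsets(offsets, p("offsets.tsv"), p("offsets.json"))
  psites <- localize_psites(kept, offsets, transcripts)
  readr::write_tsv(psites, p("psites.tsv"), progress = FALSE)

  stage <- "metagene"
  prof <- metagene_profile(psites, transcripts, anchor = "start",
                           window = config$window)
  readr::write_tsv(as_tibble(prof), p("metagene_start.tsv"), progress = FALSE)
  frames <- frame_fractions(psites)
  readr::write_tsv(frames, p("frame_fractions.tsv"), progress = FALSE)
  heat <- periodicity_heatmap(psites, transcripts, anchor = "start",
                              window = config$window)
  readr::write_tsv(as_tibble(heat), p("periodicity_heatmap_start.tsv"),
                   progress = FALSE)
  regions <- region_distribution(psites, transcripts)
  readr::write_tsv(regions, p("region_distribution.tsv"), progress = FALSE)

  stage <- "codon_occupancy"
  conditions <- config$conditions %||% unique(meta$condition)
  usage <- codon_usage(transcripts, psites, scope = "detected")
  readr::write_tsv(usage, p("codon_usage.tsv"), progress = FALSE)
  cond_of <- setNames(meta$condition, meta$library_id)
  comparisons <- list()
  for (site in c("E", "P", "A")) {
    site_usage <- codon_usage(transcripts, psites, scope = "detected",
                              site = site)
    tabs <- lapply(conditions, function(cond) {
      ps <- psites %>% filter(cond_of[.data$library_id] == cond)
      occupancy_index(ps, transcripts, site, usage = site_usage, group = cond)
    })
    for (tab in tabs) {
      readr::write_tsv(as_tibble(tab),
                       p(sprintf("codon_index_%s_%s.tsv", site,
                                 attr(tab, "group"))), progress = FALSE)
    }
    cmp <- compare_occupancy(tabs[[1L]], tabs[[2L]],
                             z_threshold = config$z_threshold)
    readr::write_tsv(as_tibble(cmp),
                     p(sprintf("occupancy_comparison_%s.tsv", site)),
                     progress = FALSE)
    comparisons[[site]] <- cmp
  }

  stage <- "expression"
  counts_all <- count_by_transcript(alignments, transcripts, "all")
  counts_cds <- count_by_transcript(alignments, transcripts, "cds_only",
                                    offsets = offsets)
  readr::write_tsv(counts_all, p("counts.tsv"), progress = FALSE)
  lens <- transcripts[, c("transcript_id", "length")]
  readr::write_tsv(fpkm(counts_all, lens), p("fpkm.tsv"), progress = FALSE)
  rna_counts <- counts_all[, c("transcript_id",
                               meta$library_id[meta$assay == "RNA"])]
  rpf_counts <- counts_cds[, c("transcript_id", rpf_libs)]
  de_rna <- de_test(rna_counts, meta, assay = "RNA",
                    conditions = conditions, alpha = config$alpha,
                    lfc = config$lfc)
  de_rpf <- de_test(rpf_counts, meta, assay = "RPF",
                    conditions = conditions, alpha = config$alpha,
                    lfc = config$lfc)
  readr::write_tsv(as_tibble(de_rna), p("de_transcriptome.tsv"),
                   progress = FALSE)
  readr::write_tsv(as_tibble(de_rpf), p("de_translatome.tsv"),
                   progress = FALSE)
  te_counts <- bind_cols(rpf_counts,
                         rna_counts[, setdiff(names(rna_counts),
                                              "transcript_id")])
  te <- translation_efficiency(te_counts, meta, conditions = conditions)
  readr::write_tsv(as_tibble(te), p("translation_efficiency.tsv"),
                   progress = FALSE)

  stage <- "report"
  report <- list(
    package_version = as.character(utils::packageVersion("riboscope")),
    config_hash = config_hash(config),
    n_libraries = nrow(meta),
    n_transcripts = nrow(transcripts),
    n_alignments = nrow(alignments),
    modal_length = attr(hist, "modal_length"),
    length_histogram = setNames(as.list(hist$count), hist$length),
    offsets = setNames(as.list(offsets$offset), offsets$length),
    frame_fractions = lapply(split(frames, frames$library_id), function(f) {
      list(f0 = f$f0, f1 = f$f1, f2 = f$f2)
    }),
    region_distribution = setNames(
      lapply(seq_len(nrow(regions)), function(i) {
        list(observed = regions$observed[i], expected = regions$expected[i])
      }), regions$region),
    occupancy = lapply(comparisons, function(cmp) {
      list(pearson_r = attr(cmp, "pearson_r"),
           outliers = cmp$codon[cmp$outlier])
    }),
    de = list(
      transcriptome = as.list(table(de_rna$call)),
      translatome = as.list(table(de_rpf$call))
    ),
    te = list(n_defined = sum(te$defined),
              n_significant = sum(te$defined & te$pvalue <= config$alpha &
                                    abs(te$delta_te) >= config$lfc,
                                  na.rm = TRUE))
  )
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, force = TRUE)
  writeLines(report_markdown(report), p("report.md"))
  stage <- NULL
  invisible(structure(report, class = "ribo_report"))
}

# Stable hash of the config: canonical JSON -> md5.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg <- cfg[order(names(cfg))]
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = 10, force = TRUE)
  md5_of_file(f)
}

report_markdown <- function(report) {
  c(
    "# riboscope run report",
    "",
    sprintf("- package version: %s", report$package_version),
    sprintf("- config hash: %s", report$config_hash),
    sprintf("- libraries: %d, transcripts: %d, alignments: %d",
            report$n_libraries, report$n_transcripts, report$n_alignments),
    sprintf("- modal footprint length: %d nt", report$modal_length),
    sprintf("- offsets: %s",
            paste(sprintf("%s:%d", names(report$offsets),
                          unlist(report$offsets)), collapse = ", ")),
    sprintf("- per-site occupancy r: %s",
            paste(sprintf("%s=%.4f", names(report$occupancy),
                          vapply(report$occupancy, `[[`, 0, "pearson_r")),
                  collapse = ", ")),
    sprintf("- DE (transcriptome): %s",
            paste(sprintf("%s=%d", names(report$de$transcriptome),
                          unlist(report$de$transcriptome)), collapse = ", ")),
    sprintf("- DE (translatome): %s",
            paste(sprintf("%s=%d", names(report$de$translatome),
                          unlist(report$de$translatome)), collapse = ", "))
  )
}
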