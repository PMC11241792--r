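# Ground-truth simulator for ribosome-profiling and RNA-seq libraries in
# transcript space. Every phenomenon the downstream stages estimate is a
# config parameter here (P-site offsets per read length, in-frame fraction,
# region weights, per-codon dwell multipliers at E/P/A, fold changes), so
# each stage can be tested by parameter recovery.

#' Default library metadata: 2 assays x 2 conditions x 2 replicates
#'
#' @param assays,conditions,replicates factors of the design.
#' @return Tibble `library_id`, `assay`, `condition`, `replicate`.
#' @export
library_metadata <- function(assays = c("RPF", "RNA"),
                             conditions = c("CK", "LT"),
                             replicates = 1:2) {
  meta <- tidyr::expand_grid(assay = assays, condition = conditions,
                             replicate = as.integer(replicates)) %>%
    mutate(library_id = paste(.data$assay, .data$condition,
                              .data$replicate, sep = "_")) %>%
    select("library_id", "assay", "condition", "replicate")
  if (anyDuplicated(meta[c("assay", "condition", "replicate")])) {
    abort("duplicate (assay, condition, replicate) triple in metadata")
  }
  meta
}

#' Simulation configuration
#'
#' Defaults emulate a plant Ribo-seq library: footprints of 28--31 nt with
#' mode 29, canonical 11--13 nt P-site offsets, strong but imperfect 3-nt
#' periodicity (85% of CDS P-sites in frame 0), CDS-dominated signal
#' (90/5/5 across CDS and UTRs), and a 3x pile-up on the start and stop
#' codons (queuing/termination pausing). Dwell multipliers default to 1
#' everywhere; perturbations (e.g. elevated AAU dwell at the E site under
#' cold stress) are injected via `dwell`.
#'
#' @param n_transcripts number of transcripts to simulate.
#' @param utr5_range,cds_range,utr3_range inclusive nt length ranges; CDS
#'   lengths are rounded to multiples of 3 (>= 9: start + one internal +
#'   stop).
#' @param length_weights named probabilities over footprint lengths.
#' @param true_offsets named per-length P-site offsets (5' end to first nt of
#'   the P-site codon).
#' @param inframe_fraction probability a CDS P-site lands in frame 0
#'   (otherwise shifted +/-1 nt, equally); in `[1/3, 1]`.
#' @param region_weights probabilities `(utr5, cds, utr3)` summing to 1.
#' @param dwell codon dwell multipliers, RNA spelling. Either a list with
#'   elements among `E`, `P`, `A` (applied to every condition), or a list
#'   keyed by condition of such lists, e.g.
#'   `list(CK = list(), LT = list(E = c(AAU = 3)))`.
#' @param start_stop_boost multiplicative dwell boost on the first and last
#'   CDS codon (set to 1 for codon-occupancy calibration runs).
#' @param codon_composition optional named probabilities over sense codons
#'   for internal CDS codons (default uniform over the 61 sense codons).
#' @param abundance per-transcript relative molar abundance (recycled;
#'   default equal, i.e. read weight proportional to feature length so the
#'   null codon-occupancy index is 1 in expectation).
#' @param fold_changes optional tibble `transcript_id`, `assay`, `condition`,
#'   `log2fc` multiplying a transcript's sampling weight in that
#'   assay/condition.
#' @param rna_insert_size fixed RNA-seq fragment length (nt).
#' @param libraries library metadata tibble (see [library_metadata()]).
#' @param reads_per_library reads simulated per library.
#' @param seed root seed; each library derives its own stream from
#'   `(seed, library_id)` so libraries are independently reproducible.
#' @return A validated config list of class `ribo_sim_config`.
#' @export
sim_config <- function(n_transcripts = 150,
                       utr5_range = c(60, 150),
                       cds_range = c(300, 900),
                       utr3_range = c(90, 210),
                       length_weights = c(`28` = 0.10, `29` = 0.60,
                                          `30` = 0.20, `31` = 0.10),
                       true_offsets = c(`28` = 11, `29` = 12,
                                        `30` = 12, `31` = 13),
                       inframe_fraction = 0.85,
                       region_weights = c(utr5 = 0.05, cds = 0.90,
                                          utr3 = 0.05),
                       dwell = NULL,
                       start_stop_boost = 3,
                       codon_composition = NULL,
                       abundance = NULL,
                       fold_changes = NULL,
                       rna_insert_size = 150,
                       libraries = library_metadata(),
                       reads_per_library = 1e5,
                       seed = 1) {
  cfg <- list(
    n_transcripts = as.integer(n_transcripts),
    utr5_range = as.integer(utr5_range), cds_range = as.integer(cds_range),
    utr3_range = as.integer(utr3_range),
    length_weights = length_weights / sum(length_weights),
    true_offsets = true_offsets,
    inframe_fraction = inframe_fraction,
    region_weights = region_weights / sum(region_weights),
    dwell = dwell, start_stop_boost = start_stop_boost,
    codon_composition = codon_composition,
    abundance = abundance, fold_changes = fold_changes,
    rna_insert_size = as.integer(rna_insert_size),
    libraries = libraries,
    reads_per_library = as.integer(reads_per_library),
    seed = as.integer(seed)
  )
  if (cfg$n_transcripts < 1L) abort("n_transcripts must be >= 1")
  if (cfg$cds_range[1L] < 9L) abort("cds_range too short for start + stop")
  if (inframe_fraction < 1 / 3 || inframe_fraction > 1) {
    abort("inframe_fraction must lie in [1/3, 1]")
  }
  lens <- as.integer(names(cfg$length_weights))
  if (!setequal(names(cfg$true_offsets), names(cfg$length_weights))) {
    abort("true_offsets and length_weights must cover the same lengths")
  }
  off <- cfg$true_offsets[names(cfg$length_weights)]
  if (any(off < 6 | off > lens - 6)) {
    abort("offsets must lie in [6, length - 6]")
  }
  if (abs(sum(cfg$region_weights) - 1) > 1e-9 || any(cfg$region_weights < 0)) {
    abort("region_weights must be non-negative and sum to 1")
  }
  if (!is.null(names(cfg$region_weights))) {
    if (!setequal(names(cfg$region_weights), REGIONS)) {
      abort("region_weights must be named utr5/cds/utr3")
    }
    cfg$region_weights <- cfg$region_weights[REGIONS]
  } else {
    names(cfg$region_weights) <- REGIONS
  }
  if (start_stop_boost <= 0) abort("start_stop_boost must be positive")
  for (d in dwell_tables(cfg)) {
    for (site in names(d)) if (any(d[[site]] <= 0)) {
      abort("dwell multipliers must be positive")
    }
  }
  structure(cfg, class = "ribo_sim_config")
}

# Resolve the dwell field into a per-condition list of E/P/A multiplier maps.
dwell_tables <- function(config) {
  dwell <- config$dwell
  conds <- unique(config$libraries$condition)
  if (is.null(dwell)) return(setNames(rep(list(list()), length(conds)), conds))
  if (all(names(dwell) %in% c("E", "P", "A"))) {
    return(setNames(rep(list(dwell), length(conds)), conds))
  }
  out <- setNames(rep(list(list()), length(conds)), conds)
  for (nm in names(dwell)) out[[nm]] <- dwell[[nm]]
  out
}

#' Simulate a transcriptome with valid CDS geometry
#'
#' Each CDS starts with AUG, ends with a stop codon, and contains no internal
#' in-frame stop; UTRs are uniform over A/C/G/T, internal codons follow
#' `codon_composition` (default uniform over the 61 sense codons).
#'
#' @param config a [sim_config()].
#' @return A transcript-model tibble (see [transcript_models()]).
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "ribo_sim_config"))
  with_seed(derive_seed(config$seed, "transcriptome"), {
    n <- config$n_transcripts
    comp <- config$codon_composition
    if (is.null(comp)) {
      comp <- setNames(rep(1, 61L), to_rna(sense_codons_dna()))
    }
    comp <- comp[!is_stop_codon(names(comp))]
    if (!length(comp) || any(comp < 0)) {
      abort("codon_composition must give non-negative weight to sense codons")
    }
    comp_codons <- to_dna(names(comp))
    comp_p <- comp / sum(comp)
    rng_len <- function(rg, k) {
      if (rg[1L] == rg[2L]) rep(rg[1L], k) else sample(rg[1L]:rg[2L], k, TRUE)
    }
    utr5 <- rng_len(config$utr5_range, n)
    utr3 <- rng_len(config$utr3_range, n)
    cds <- pmax(9L, (rng_len(config$cds_range, n) %/% 3L) * 3L)
    seqs <- character(n)
    for (i in seq_len(n)) {
      n_internal <- cds[i] %/% 3L - 2L
      internal <- sample(comp_codons, n_internal, TRUE, prob = comp_p)
      seqs[i] <- paste0(
        paste0(sample(BASES, utr5[i], TRUE), collapse = ""),
        START_CODON_DNA,
        paste0(internal, collapse = ""),
        sample(STOP_CODONS_DNA, 1L),
        paste0(sample(BASES, utr3[i], TRUE), collapse = "")
      )
    }
    transcript_models(
      transcript_id = sprintf("t%04d", seq_len(n)),
      sequence = seqs,
      cds_start = utr5,
      cds_end = utr5 + cds
    )
  })
}

# Per-transcript codon-position sampling weights for one condition:
# weight(j) = E(codon_{j-1}) * P(codon_j) * A(codon_{j+1}) * boost(first/last).
psite_weight_list <- function(transcripts, config, condition) {
  dw <- dwell_tables(config)[[condition]] %||% list()
  mult <- function(site, codons_rna) {
    w <- rep(1, length(codons_rna))
    tab <- dw[[site]]
    if (!is.null(tab)) {
      hit <- match(codons_rna, names(tab))
      w[!is.na(hit)] <- tab[hit[!is.na(hit)]]
    }
    w
  }
  lapply(seq_len(nrow(transcripts)), function(i) {
    cds_seq <- substr(transcripts$sequence[i], transcripts$cds_start[i] + 1L,
                      transcripts$cds_end[i])
    cod <- to_rna(split_codons(cds_seq))
    k <- length(cod)
    w <- mult("P", cod)
    w <- w * c(1, mult("E", cod[-k]))        # E neighbor: codon j-1
    w <- w * c(mult("A", cod[-1L]), 1)       # A neighbor: codon j+1
    w[c(1L, k)] <- w[c(1L, k)] * config$start_stop_boost
    w
  })
}

# Per-transcript sampling weight for one library (abundance x fold change x
# feature length).
library_weights <- function(transcripts, config, library) {
  ab <- config$abundance %||% 1
  ab <- rep_len(ab, nrow(transcripts))
  len <- if (library$assay == "RPF") transcripts$cds_len else transcripts$length
  w <- ab * len
  fc <- config$fold_changes
  if (!is.null(fc)) {
    hit <- fc[fc$assay == library$assay & fc$condition == library$condition, ]
    idx <- match(hit$transcript_id, transcripts$transcript_id)
    w[idx[!is.na(idx)]] <- w[idx[!is.na(idx)]] * 2^hit$log2fc[!is.na(idx)]
  }
  w
}

#' Simulate one library of footprint (or RNA-seq) alignments
#'
#' RPF reads are drawn transcript -> region -> dwell-weighted P-site codon ->
#' frame jitter -> length -> 5' end (`five_prime = psite - offset[length]`).
#' RNA reads are unstructured: uniform 5' ends at a fixed insert size.
#' Reads whose 5' end would fall outside the transcript are resampled and
#' counted.
#'
#' @param transcripts transcript models (from [simulate_transcriptome()]).
#' @param config a [sim_config()].
#' @param library one row of the library metadata.
#' @return Alignment tibble with attribute `truth`: the realized draws
#'   (P-site positions, regions, frame shifts), per-transcript read counts,
#'   and the resample count.
#' @export
simulate_library <- function(transcripts, config, library) {
  stopifnot(inherits(config, "ribo_sim_config"))
  library <- as.list(library)
  with_seed(derive_seed(config$seed, library$library_id), {
    n <- config$reads_per_library
    w_t <- library_weights(transcripts, config, library)
    if (library$assay == "RNA") {
      ins <- config$rna_insert_size
      w_t[transcripts$length < ins] <- 0
      if (all(w_t == 0)) abort("no transcript long enough for rna_insert_size")
      tr <- sample.int(nrow(transcripts), n, TRUE, prob = w_t)
      fp <- floor(runif(n) * (transcripts$length[tr] - ins + 1L))
      aln <- tibble(transcript_id = transcripts$transcript_id[tr],
                    five_prime = as.integer(fp),
                    length = rep(ins, n),
                    library_id = rep(library$library_id, n))
      truth <- list(library = library, n_resampled = 0L,
                    per_transcript = count(aln, .data$transcript_id))
      return(structure(aln, truth = truth))
    }
    wl <- psite_weight_list(transcripts, config, library$condition)
    lens <- as.integer(names(config$length_weights))
    offs <- as.integer(config$true_offsets[names(config$length_weights)])
    rho <- config$inframe_fraction
    rw <- config$region_weights
    draw <- function(k) {
      tr <- sample.int(nrow(transcripts), k, TRUE, prob = w_t)
      li <- sample.int(length(lens), k, TRUE, prob = config$length_weights)
      L <- lens[li]
      off <- offs[li]
      region <- sample(REGIONS, k, TRUE, prob = rw)
      psite <- integer(k)
      shift <- integer(k)
      cds_idx <- which(region == "cds")
      for (grp in split(cds_idx, tr[cds_idx])) {
        t1 <- tr[grp[1L]]
        kk <- length(grp)
        cp <- sample.int(length(wl[[t1]]), kk, TRUE, prob = wl[[t1]])
        psite[grp] <- transcripts$cds_start[t1] + 3L * (cp - 1L)
      }
      off_frame <- cds_idx[runif(length(cds_idx)) >= rho]
      shift[off_frame] <- sample(c(-1L, 1L), length(off_frame), TRUE)
      # UTR positions are drawn where the footprint fits on the transcript
      # (5' end >= 0 and 3' end within bounds), so region_weights are the
      # realized region distribution, not an upper bound.
      i5 <- which(region == "utr5")
      span5 <- transcripts$utr5_len[tr[i5]] - off[i5]
      psite[i5] <- off[i5] + as.integer(floor(runif(length(i5)) *
                                                pmax(span5, 0L)))
      psite[i5][span5 <= 0L] <- -1L      # no room: resampled below
      i3 <- which(region == "utr3")
      hi3 <- pmin(transcripts$length[tr[i3]] - L[i3] + off[i3],
                  transcripts$length[tr[i3]] - 1L)
      span3 <- hi3 - transcripts$cds_end[tr[i3]] + 1L
      psite[i3] <- transcripts$cds_end[tr[i3]] +
        as.integer(floor(runif(length(i3)) * pmax(span3, 0L)))
      psite[i3][span3 <= 0L] <- -1L
      psite <- psite + shift
      tibble(tr = tr, region = region, psite = psite, shift = shift,
             length = L, five_prime = psite - off)
    }
    reads <- draw(n)
    n_resampled <- 0L
    for (iter in seq_len(100L)) {
      bad <- which(reads$five_prime < 0L |
                     reads$five_prime + reads$length >
                       transcripts$length[reads$tr] |
                     reads$psite < 0L |
                     reads$psite >= transcripts$length[reads$tr])
      if (!length(bad)) break
      n_resampled <- n_resampled + length(bad)
      reads[bad, ] <- draw(length(bad))
    }
    aln <- tibble(transcript_id = transcripts$transcript_id[reads$tr],
                  five_prime = as.integer(reads$five_prime),
                  length = as.integer(reads$length),
                  library_id = rep(library$library_id, n))
    truth <- list(
      library = library,
      n_resampled = n_resampled,
      psite = reads$psite, region = reads$region, shift = reads$shift,
      per_transcript = count(aln, .data$transcript_id)
    )
    structure(aln, truth = truth)
  })
}

#' Simulate the full dataset described by a config
#'
#' @param config a [sim_config()].
#' @return List with `transcripts`, `alignments` (all libraries bound),
#'   `meta`, `truth` (per-library ground truth), and the `config`.
#' @export
simulate_dataset <- function(config) {
  transcripts <- simulate_transcriptome(config)
  libs <- split(config$libraries, seq_len(nrow(config$libraries)))
  sims <- lapply(libs, function(l) simulate_library(transcripts, config, l))
  truth <- lapply(sims, attr, "truth")
  names(truth) <- config$libraries$library_id
  list(transcripts = transcripts,
       alignments = bind_rows(lapply(sims, as_tibble)),
       meta = config$libraries,
       truth = truth,
       config = config)
}

#' Write a simulated dataset to disk with a checksummed manifest
#'
#' Emits transcript FASTA, annotation TSV, one alignment TSV per library,
#' library metadata TSV, a ground-truth JSON, and a manifest JSON listing
#' every file with its MD5 checksum.
#'
#' @param dataset result of [simulate_dataset()].
#' @param out_dir output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_transcripts(dataset$transcripts, p("transcripts.fa"),
                    p("annotation.tsv"))
  readr::write_tsv(dataset$meta, p("libraries.tsv"), progress = FALSE)
  lib_files <- character(0)
  for (lib in dataset$meta$library_id) {
    f <- p(paste0(lib, ".alignments.tsv"))
    write_alignments(dplyr::filter(dataset$alignments,
                                   .data$library_id == lib), f)
    lib_files <- c(lib_files, f)
  }
  truth <- lapply(dataset$truth, function(tt) {
    tt$psite <- NULL; tt$region <- NULL; tt$shift <- NULL  # keep JSON small
    tt
  })
  cfg <- unclass(dataset$config)
  cfg$libraries <- NULL
  jsonlite::write_json(list(config = cfg, libraries = truth),
                       p("ground_truth.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  files <- c(p("transcripts.fa"), p("annotation.tsv"), p("libraries.tsv"),
             lib_files, p("ground_truth.json"))
  manifest <- list(files = lapply(files, function(f) {
    list(path = basename(f), md5 = md5_of_file(f))
  }))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Simulate negative-binomial count matrices for DE / TE calibration
#'
#' Count-level companion to the read-level simulator: per-transcript NB
#' counts with a common dispersion, optional per-library depth factors, and
#' optional condition/assay-specific log2 fold changes.
#'
#' @param n_transcripts number of features.
#' @param meta library metadata tibble.
#' @param baseline_mean scalar or per-transcript NB mean at depth 1.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param log2fc optional tibble `transcript_id`, `assay`, `condition`,
#'   `log2fc`.
#' @param depth_factors optional named per-library depth multipliers.
#' @param seed RNG seed.
#' @return List `counts` (wide tibble) and `truth` (the realized settings).
#' @export
simulate_counts <- function(n_transcripts, meta, baseline_mean = 100,
                            dispersion = 0.05, log2fc = NULL,
                            depth_factors = NULL, seed = 1) {
  with_seed(derive_seed(seed, "counts"), {
    ids <- sprintf("g%05d", seq_len(n_transcripts))
    mu0 <- rep_len(baseline_mean, n_transcripts)
    counts <- tibble(transcript_id = ids)
    for (i in seq_len(nrow(meta))) {
      mu <- mu0
      if (!is.null(log2fc)) {
        hit <- log2fc[log2fc$assay == meta$assay[i] &
                        log2fc$condition == meta$condition[i], ]
        idx <- match(hit$transcript_id, ids)
        mu[idx[!is.na(idx)]] <- mu[idx[!is.na(idx)]] * 2^hit$log2fc[!is.na(idx)]
      }
      if (!is.null(depth_factors)) {
        mu <- mu * depth_factors[[meta$library_id[i]]]
      }
      counts[[meta$library_id[i]]] <- if (dispersion > 0) {
        rnbinom(n_transcripts, mu = mu, size = 1 / dispersion)
      } else {
        stats::rpois(n_transcripts, mu)
      }
    }
    list(counts = counts,
         truth = list(baseline_mean = baseline_mean, dispersion = dispersion,
                      log2fc = log2fc, depth_factors = depth_factors,
                      seed = seed))
  })
}
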