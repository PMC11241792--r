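# Shared constants and small helpers: the codon universe, DNA/RNA spelling,
# deterministic per-library seeds, and coordinate conventions (0-based,
# half-open everywhere internally; 1-based formats are converted at I/O).

BASES <- c("A", "C", "G", "T")

#' All 64 codons
#'
#' @param spelling `"dna"` (T) or `"rna"` (U). Internally sequences are DNA;
#'   codon tables are reported in RNA spelling to match ribosome-profiling
#'   convention (AUG, AAU, ...).
#' @return Character vector of 64 codons, alphabetical.
#' @export
all_codons <- function(spelling = c("rna", "dna")) {
  spelling <- match.arg(spelling)
  cod <- sort(apply(expand.grid(BASES, BASES, BASES), 1L, paste0, collapse = ""))
  if (spelling == "rna") to_rna(cod) else cod
}

STOP_CODONS_DNA <- c("TAA", "TAG", "TGA")
START_CODON_DNA <- "ATG"

sense_codons_dna <- function() setdiff(all_codons("dna"), STOP_CODONS_DNA)

#' Convert codon/sequence spelling between DNA and RNA alphabets
#'
#' @param x character vector of sequences or codons.
#' @return `to_rna()` replaces T with U; `to_dna()` replaces U with T.
#' @export
to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname to_rna
#' @export
to_dna <- function(x) chartr("Uu", "Tt", x)

is_stop_codon <- function(codon_rna) codon_rna %in% to_rna(STOP_CODONS_DNA)

# Deterministic 31-bit seed derived from a root seed and a string key, so each
# simulated library has its own reproducible stream.
derive_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (v in utf8ToInt(as.character(key))) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Region of a 0-based position relative to half-open CDS [cds_start, cds_end).
region_of <- function(pos, cds_start, cds_end) {
  dplyr::case_when(
    pos < cds_start ~ "utr5",
    pos < cds_end ~ "cds",
    TRUE ~ "utr3"
  )
}

REGIONS <- c("utr5", "cds", "utr3")

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Split a CDS (DNA string, length multiple of 3) into its codons.
split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
}

md5_of_file <- function(path) unname(tools::md5sum(path))
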