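#' Simulate amplicon sequencing reads for a barcoded library
#'
#' Draws DNA-sample reads multinomially from the programmed library
#' frequencies and RNA-sample reads from frequencies proportional to
#' DNA frequency x programmed activity (renormalized), then renders each
#' draw as an amplicon read: random 5' pad, anchor, offset bases, barcode,
#' random 3' pad. A fraction of reads are anchor-free junk, emulating
#' off-target amplification. Entries listed in `dropout` receive zero mass
#' in both analytes, emulating elements lost to failed synthesis.
#'
#' @param library Enhancer library ([make_library()]).
#' @param truth Ground truth ([make_ground_truth()]).
#' @param layout Amplicon layout ([amplicon_layout()]).
#' @param depth_rna,depth_dna Total reads per analyte (> 0).
#' @param dropout Character vector of `enhancer_id`s with zero abundance.
#' @param anchorless_fraction Fraction of junk reads without the anchor,
#'   in `[0, 1)`; exactly `round(fraction * depth)` junk reads are emitted.
#' @param pad5 Length of the random 5' pad preceding the anchor.
#' @param pad3 Length of the random 3' pad following the barcode.
#' @param error_rate Optional uniform per-base substitution rate (default 0).
#' @param seed Integer seed; defaults to the ground-truth seed. Reads are
#'   deterministic per seed via [derive_seed()] sub-streams.
#' @return A list of class `mpra_read_sim`: `rna` and `dna` (character read
#'   vectors), `manifest` (per-sample depth and junk tallies), and
#'   `expected_frequency` (the renormalized sampling frequencies used).
#' @export
simulate_reads <- function(library, truth, layout, depth_rna, depth_dna,
                           dropout = character(), anchorless_fraction = 0,
                           pad5 = 8L, pad3 = 12L, error_rate = 0,
                           seed = attr(truth, "seed")) {
  validate_library(library)
  stopifnot(inherits(layout, "amplicon_layout"),
            depth_rna > 0, depth_dna > 0,
            anchorless_fraction >= 0, anchorless_fraction < 1,
            error_rate >= 0, error_rate < 1)
  if (layout$barcode_length != unique(nchar(library$barcode))) {
    stop("layout barcode_length does not match the library barcode length")
  }
  if (!all(dropout %in% library$enhancer_id)) {
    stop("dropout ids not present in the library")
  }
  tr <- truth[match(library$barcode, truth$barcode), ]
  p_dna <- tr$dna_frequency
  p_dna[tr$enhancer_id %in% dropout] <- 0
  if (sum(p_dna) <= 0) stop("dropout removed all library mass")
  p_dna <- p_dna / sum(p_dna)
  p_rna <- p_dna * tr$activity
  p_rna <- p_rna / sum(p_rna)

  one <- function(p, depth, sub_seed) {
    n_junk <- round(anchorless_fraction * depth)
    n_real <- depth - n_junk
    withr::with_seed(sub_seed, {
      counts <- as.integer(rmultinom(1, n_real, p))
      bc <- rep(library$barcode, times = counts)
      # pads are drawn from a pool of random sequences; they only need to
      # look like flanking sequence, not be unique per read
      pool <- function(width) {
        if (width == 0) return("")
        random_dna(min(4096L, n_real), width)[
          sample.int(min(4096L, n_real), n_real, replace = TRUE)]
      }
      reads <- paste0(pool(pad5), layout$anchor,
                      pool(layout$barcode_offset), bc, pool(pad3))
      if (error_rate > 0) reads <- add_read_errors(reads, error_rate)
      read_width <- pad5 + nchar(layout$anchor) + layout$barcode_offset +
        layout$barcode_length + pad3
      junk <- junk_reads(n_junk, read_width, layout$anchor)
      all_reads <- c(reads, junk)
      if (layout$orientation == "reverse_complement") {
        all_reads <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(all_reads)))
      }
      all_reads[sample.int(length(all_reads))]
    })
  }
  rna <- one(p_rna, depth_rna, derive_seed(seed, 1L))
  dna <- one(p_dna, depth_dna, derive_seed(seed, 2L))
  manifest <- tibble::tibble(
    sample_id = c("RNA_1", "DNA_1"),
    analyte = c("RNA", "DNA"),
    depth = c(as.integer(depth_rna), as.integer(depth_dna)),
    n_anchorless = c(round(anchorless_fraction * depth_rna),
                     round(anchorless_fraction * depth_dna)))
  structure(list(rna = rna, dna = dna, manifest = manifest,
                 expected_frequency = tibble::tibble(
                   enhancer_id = tr$enhancer_id, barcode = tr$barcode,
                   dna = p_dna, rna = p_rna)),
            class = "mpra_read_sim")
}

# anchor-free random reads; regenerate any that happen to contain the anchor
junk_reads <- function(n, width, anchor, max_retries = 50L) {
  if (n == 0) return(character(0))
  reads <- random_dna(n, width)
  for (i in seq_len(max_retries)) {
    bad <- grepl(anchor, reads, fixed = TRUE)
    if (!any(bad)) return(reads)
    reads[bad] <- random_dna(sum(bad), width)
  }
  stop("could not generate anchor-free junk reads")
}

# uniform per-base substitutions at the given rate
add_read_errors <- function(reads, rate) {
  chars <- strsplit(reads, "", fixed = TRUE)
  unlist(lapply(chars, function(x) {
    hit <- runif(length(x)) < rate
    if (any(hit)) x[hit] <- sample(DNA_BASES, sum(hit), replace = TRUE)
    paste0(x, collapse = "")
  }))
}

#' @importFrom stats runif
NULL

#' Write reads to a FASTQ file
#'
#' Writes 4-line FASTQ records with constant Phred+33 qualities ("I", Q40).
#' A path ending in `.gz` is gzip-compressed.
#'
#' @param reads Character vector of read sequences.
#' @param path Output path.
#' @param prefix Read-name prefix.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, prefix = "read") {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- paste0(prefix, "_", seq_along(reads))
  q <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Read a FASTQ file into a character vector of sequences
#'
#' @param path FASTQ path (optionally gzipped).
#' @return Character vector of read sequences.
#' @export
read_fastq <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Write a library manifest TSV
#'
#' @param library Enhancer library.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library_tsv <- function(library, path) {
  write.table(library, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a library manifest TSV
#'
#' @param path Path written by [write_library_tsv()].
#' @return A validated library tibble.
#' @export
read_library_tsv <- function(path) {
  out <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  validate_library(out)
  out
}
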