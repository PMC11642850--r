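#' Count library barcodes in amplicon reads
#'
#' For each read the constant anchor is located (exact substring match; the
#' first occurrence is used if a read contains it twice). The
#' `barcode_length` bases starting `barcode_offset` bases after the anchor
#' end are matched against the library whitelist. Reads without the anchor
#' are tallied as `no_anchor`; reads whose barcode window runs past the read
#' end as `barcode_truncated`; anchored reads with an off-whitelist barcode
#' as `unmatched_barcode`. With `orientation = "reverse_complement"` reads
#' are reverse-complemented before the search. Per sample,
#' `matched + discarded` equals the number of reads processed.
#'
#' @param reads A character vector of read sequences, a
#'   `Biostrings::DNAStringSet`, a path to a FASTQ(.gz) file, or a named
#'   list of any of these (one element per sample).
#' @param library Enhancer library ([make_library()]).
#' @param layout Amplicon layout ([amplicon_layout()]).
#' @param max_mismatch Anchor mismatches tolerated (0, the default, is an
#'   exact match; 1 enables a one-mismatch search).
#' @param sample_id Sample name used when `reads` is a single sample.
#' @return An object of class `barcode_counts`: `counts` (integer matrix,
#'   barcodes x samples), `discarded` (tibble of per-sample discard
#'   tallies) and `total_reads` (named integer vector).
#' @examples
#' lib <- make_library(2, 1, 0, barcode_length = 8, seed = 1)
#' lay <- amplicon_layout("ACGTACGTAC", 0, 8)
#' reads <- paste0("ACGTACGTAC", lib$barcode)
#' extract_barcodes(reads, lib, lay)$counts
#' @export
extract_barcodes <- function(reads, library, layout, max_mismatch = 0L,
                             sample_id = "sample_1") {
  validate_library(library)
  stopifnot(inherits(layout, "amplicon_layout"))
  if (nrow(library) > 0 &&
      layout$barcode_length != unique(nchar(library$barcode))) {
    stop("layout barcode_length does not match the library barcode length")
  }
  if (is.list(reads) && !inherits(reads, "DNAStringSet")) {
    if (is.null(names(reads))) stop("multi-sample reads must be named")
    per <- lapply(names(reads), function(s) {
      extract_barcodes(reads[[s]], library, layout,
                       max_mismatch = max_mismatch, sample_id = s)
    })
    return(bind_barcode_counts(per))
  }
  seqs <- as_read_chars(reads)
  n <- length(seqs)
  if (layout$orientation == "reverse_complement" && n > 0) {
    seqs <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs)))
  }
  pos <- anchor_position(seqs, layout$anchor, max_mismatch)
  no_anchor <- pos < 0
  start <- pos + nchar(layout$anchor) + layout$barcode_offset
  end <- start + layout$barcode_length - 1L
  truncated <- !no_anchor & end > nchar(seqs)
  usable <- !no_anchor & !truncated
  bc <- substr(seqs[usable], start[usable], end[usable])
  idx <- match(bc, library$barcode)
  counts <- matrix(tabulate(idx[!is.na(idx)], nbins = nrow(library)),
                   ncol = 1,
                   dimnames = list(library$barcode, sample_id))
  storage.mode(counts) <- "integer"
  discarded <- tibble::tibble(sample_id = sample_id,
                              no_anchor = sum(no_anchor),
                              barcode_truncated = sum(truncated),
                              unmatched_barcode = sum(is.na(idx)))
  structure(list(counts = counts, discarded = discarded,
                 total_reads = setNames(n, sample_id)),
            class = "barcode_counts")
}

# normalize the read input forms to a character vector
as_read_chars <- function(reads) {
  if (inherits(reads, "DNAStringSet")) return(as.character(reads))
  stopifnot(is.character(reads))
  if (length(reads) == 1 && file.exists(reads) &&
      grepl("\\.(fastq|fq)(\\.gz)?$", reads)) {
    return(read_fastq(reads))
  }
  reads
}

# first anchor position per read (-1 when absent); optional 1-mismatch mode
anchor_position <- function(seqs, anchor, max_mismatch) {
  if (length(seqs) == 0) return(integer(0))
  if (max_mismatch == 0) {
    return(regexpr(anchor, seqs, fixed = TRUE))
  }
  hits <- Biostrings::vmatchPattern(anchor, Biostrings::DNAStringSet(seqs),
                                    max.mismatch = max_mismatch)
  vapply(Biostrings::startIndex(hits), function(s) {
    if (is.null(s)) -1L else s[1]
  }, integer(1))
}

#' Combine single-sample barcode count tables
#'
#' @param tables List of `barcode_counts` objects over the same library.
#' @return A multi-sample `barcode_counts` object.
#' @export
bind_barcode_counts <- function(tables) {
  stopifnot(length(tables) >= 1,
            all(vapply(tables, inherits, logical(1), "barcode_counts")))
  counts <- do.call(cbind, lapply(tables, `[[`, "counts"))
  discarded <- do.call(rbind, lapply(tables, `[[`, "discarded"))
  total <- do.call(c, lapply(tables, `[[`, "total_reads"))
  structure(list(counts = counts, discarded = discarded,
                 total_reads = total),
            class = "barcode_counts")
}

#' Convert barcode counts to reads per million
#'
#' `value = count / column_total * 1e6`, per sample. Column totals are
#' matched reads only; each output column sums to one million.
#'
#' @param x A `barcode_counts` object or a nonnegative count matrix
#'   (barcodes x samples).
#' @return A numeric matrix in RPM (equivalently CPM) units.
#' @export
counts_to_rpm <- function(x) {
  m <- if (inherits(x, "barcode_counts")) x$counts else as.matrix(x)
  stopifnot(all(m >= 0))
  tot <- colSums(m)
  if (any(tot == 0)) {
    bad <- colnames(m)[tot == 0] %||% which(tot == 0)
    stop("sample(s) with zero matched reads: ", paste(bad, collapse = ", "))
  }
  sweep(m, 2, tot, "/") * 1e6
}

#' Per-element RNA:DNA activity
#'
#' Replicate RPM columns are averaged within each analyte first, then
#' `activity = (mean RNA RPM + pseudocount) / (mean DNA RPM + pseudocount)`
#' per barcode. With a zero pseudocount, rows with zero DNA are flagged
#' `zero_dna` and their activity set to `NA` rather than infinite.
#'
#' @param rna_rpm,dna_rpm RPM matrices from [counts_to_rpm()] with barcode
#'   rownames; they must share a barcode index.
#' @param library Enhancer library mapping barcodes to elements.
#' @param pseudocount_rpm Pseudocount added to both means (default 0).
#' @return An activity tibble with `enhancer_id`, `class`, optional
#'   `promoter_id`, `barcode`, `rna_rpm`, `dna_rpm`, `activity`,
#'   `normalized_activity` (`NA` until [normalize_activity()]) and `flags`.
#' @export
compute_activity <- function(rna_rpm, dna_rpm, library, pseudocount_rpm = 0) {
  validate_library(library)
  stopifnot(pseudocount_rpm >= 0)
  common <- intersect(rownames(rna_rpm), rownames(dna_rpm))
  common <- intersect(common, library$barcode)
  if (length(common) == 0) {
    stop("RNA and DNA tables share no library barcodes")
  }
  rna_mean <- rowMeans(rna_rpm[common, , drop = FALSE])
  dna_mean <- rowMeans(dna_rpm[common, , drop = FALSE])
  lib <- library[match(common, library$barcode), ]
  act <- (rna_mean + pseudocount_rpm) / (dna_mean + pseudocount_rpm)
  flags <- ifelse(dna_mean == 0 & pseudocount_rpm == 0, "zero_dna",
                  ifelse(pseudocount_rpm > 0, "pseudocounted", ""))
  act[flags == "zero_dna"] <- NA_real_
  out <- tibble::tibble(enhancer_id = lib$enhancer_id, class = lib$class,
                        barcode = common,
                        rna_rpm = unname(rna_mean),
                        dna_rpm = unname(dna_mean),
                        activity = unname(act),
                        normalized_activity = NA_real_,
                        flags = unname(flags))
  if ("promoter_id" %in% names(lib)) {
    out$promoter_id <- lib$promoter_id
    out <- out[, c("enhancer_id", "class", "promoter_id", "barcode",
                   "rna_rpm", "dna_rpm", "activity", "normalized_activity",
                   "flags")]
  }
  out
}

#' Rescale activities so a reference class averages one
#'
#' Within each stratum (each `promoter_id` when present, otherwise the whole
#' table) all activities are multiplied by one scalar adjustment factor
#' chosen so that the mean activity of the reference class equals one. The
#' single shared factor preserves every within-stratum activity ratio, and
#' the operation is idempotent.
#'
#' @param table Activity tibble from [compute_activity()].
#' @param reference_class Class whose mean is pinned to one (default
#'   `"endothelial"`, the negative-control enhancer group).
#' @return The table with `normalized_activity` filled in; the per-stratum
#'   factors are attached as attribute `"adjustment_factors"`.
#' @export
normalize_activity <- function(table, reference_class = "endothelial") {
  stopifnot(is.data.frame(table),
            all(c("class", "activity", "flags") %in% names(table)))
  strata <- if ("promoter_id" %in% names(table)) table$promoter_id
            else rep("all", nrow(table))
  out <- table
  factors <- c()
  for (s in unique(strata)) {
    i <- strata == s
    ref <- i & table$class == reference_class & table$flags != "zero_dna" &
      is.finite(table$activity)
    if (!any(ref)) {
      stop("no usable ", reference_class, " rows in stratum '", s, "'")
    }
    f <- 1 / mean(table$activity[ref])
    out$normalized_activity[i] <- table$activity[i] * f
    factors[s] <- f
  }
  attr(out, "adjustment_factors") <- factors
  out
}

#' Episomal DNA-abundance filter
#'
#' A promoter--enhancer pair is kept only if its DNA abundance is strictly
#' above `min_cpm` in every DNA replicate.
#'
#' @param dna_cpm CPM matrix, pairs (rows) x DNA replicates (columns).
#' @param min_cpm Threshold (default 30; the comparison is strict `>`).
#' @return Named logical vector (`TRUE` = kept), with the kept rownames as
#'   attribute `"keep"`.
#' @export
filter_episomal <- function(dna_cpm, min_cpm = 30) {
  m <- as.matrix(dna_cpm)
  stopifnot(ncol(m) >= 1)
  kept <- rowSums(m > min_cpm) == ncol(m)
  names(kept) <- rownames(m)
  attr(kept, "keep") <- rownames(m)[kept]
  kept
}

#' Squared Pearson correlation between replicate frequency vectors
#'
#' @param freq_a,freq_b Per-barcode frequencies (aligned by names when
#'   named), length >= 3.
#' @return r-squared in `[0, 1]`, or `NA` with a warning when either vector
#'   has zero variance.
#' @export
replicate_correlation <- function(freq_a, freq_b) {
  if (!is.null(names(freq_a)) && !is.null(names(freq_b))) {
    common <- intersect(names(freq_a), names(freq_b))
    freq_a <- freq_a[common]
    freq_b <- freq_b[common]
  }
  stopifnot(length(freq_a) == length(freq_b), length(freq_a) >= 3)
  if (sd(freq_a) == 0 || sd(freq_b) == 0) {
    warning("zero variance in a frequency vector; correlation undefined")
    return(NA_real_)
  }
  cor(freq_a, freq_b)^2
}

#' Fold change between class mean activities
#'
#' `mean(class_a) / mean(class_b)`, computed on normalized activity when
#' available (the ratio is identical either way within a stratum because
#' normalization is a single shared factor). Flagged rows are excluded.
#'
#' @param table Activity tibble.
#' @param class_a,class_b Class labels (numerator, denominator).
#' @return A single positive number.
#' @export
group_fold_change <- function(table, class_a = "cardiomyocyte",
                              class_b = "endothelial") {
  vals <- if (all(is.na(table$normalized_activity))) table$activity
          else table$normalized_activity
  ok <- table$flags != "zero_dna" & is.finite(vals)
  a <- vals[ok & table$class == class_a]
  b <- vals[ok & table$class == class_b]
  if (length(a) == 0) stop("no usable rows of class '", class_a, "'")
  if (length(b) == 0) stop("no usable rows of class '", class_b, "'")
  mean(a) / mean(b)
}

#' Compare per-element activities between two assays
#'
#' Inner-joins two activity tables on `enhancer_id` (flagged rows dropped)
#' and reports the squared Pearson correlation and the ordinary
#' least-squares fit of assay B on assay A, along with the joined table.
#'
#' @param a,b Activity tibbles (e.g. integrated vs episomal assays).
#' @param value Column to compare (default `"activity"`).
#' @return A list with `r_squared`, `slope`, `intercept`, `n` and `data`.
#' @export
compare_assays <- function(a, b, value = "activity") {
  keep <- function(x) x[x$flags != "zero_dna" & is.finite(x[[value]]), ]
  a <- keep(a)
  b <- keep(b)
  joined <- merge(a[, c("enhancer_id", value)], b[, c("enhancer_id", value)],
                  by = "enhancer_id", suffixes = c("_a", "_b"))
  if (nrow(joined) < 3) {
    stop("fewer than 3 elements shared between the assays")
  }
  va <- joined[[paste0(value, "_a")]]
  vb <- joined[[paste0(value, "_b")]]
  fit <- lm(vb ~ va)
  list(r_squared = cor(va, vb)^2,
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       n = nrow(joined),
       data = tibble::as_tibble(joined))
}

#' Write an activity table TSV
#'
#' @param table Activity tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_activity_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pre-made count table TSV (barcode rows, sample columns)
#'
#' @param path TSV with a `barcode` first column.
#' @return Integer count matrix with barcode rownames.
#' @export
read_count_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  stopifnot(names(df)[1] == "barcode")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$barcode
  storage.mode(m) <- "integer"
  m
}
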