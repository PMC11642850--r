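ENHANCER_CLASSES <- c("cardiomyocyte", "endothelial", "esc")

#' Build a barcoded enhancer library
#'
#' Generates an enhancer/barcode manifest for a reporter-assay library made
#' of three element classes: candidate cardiomyocyte enhancers, negative
#' control endothelial/endocardial enhancers, and negative control regions
#' bound by P300 in embryonic stem cells. Each entry receives a unique random
#' barcode. In episomal mode (`promoters` given) every promoter--enhancer
#' combination is a separate entry with its own barcode.
#'
#' @param n_cm,n_endo,n_esc Number of cardiomyocyte, endothelial and ESC
#'   entries (default 25/25/5, the composition of a 55-element pool).
#' @param barcode_length Barcode length in bases (>= 6).
#' @param seed Integer seed; output is deterministic for a fixed seed.
#' @param promoters Optional character vector of promoter identifiers; when
#'   given, entries are the full promoter x enhancer cross.
#' @return A tibble with columns `enhancer_id`, `class`, `barcode` and, in
#'   episomal mode, `promoter_id`.
#' @examples
#' lib <- make_library(25, 25, 5, barcode_length = 16, seed = 1)
#' table(lib$class)
#' @export
make_library <- function(n_cm = 25, n_endo = 25, n_esc = 5,
                         barcode_length = 16, seed, promoters = NULL) {
  stopifnot(n_cm >= 0, n_endo >= 0, n_esc >= 0)
  if (barcode_length < 6) stop("barcode_length must be >= 6")
  ids <- c(sprintf("CM_%02d", seq_len(n_cm)),
           sprintf("ENDO_%02d", seq_len(n_endo)),
           sprintf("ESC_%02d", seq_len(n_esc)))
  cls <- rep(ENHANCER_CLASSES, times = c(n_cm, n_endo, n_esc))
  if (!is.null(promoters)) {
    stopifnot(is.character(promoters), length(promoters) >= 1)
    idx <- rep(seq_along(ids), times = length(promoters))
    prom <- rep(promoters, each = length(ids))
    ids <- ids[idx]
    cls <- cls[idx]
  }
  n <- length(ids)
  bc <- withr::with_seed(as.integer(seed), unique_barcodes(n, barcode_length))
  out <- tibble::tibble(enhancer_id = ids, class = cls, barcode = bc)
  if (!is.null(promoters)) {
    out$promoter_id <- prom
    out <- out[, c("enhancer_id", "class", "promoter_id", "barcode")]
  }
  out
}

# unique random barcodes with bounded duplicate-rejection retries
unique_barcodes <- function(n, width, max_retries = 25L) {
  if (n == 0) return(character(0))
  if (4^width < n) stop("barcode space too small for ", n, " unique barcodes")
  bc <- random_dna(n, width)
  for (i in seq_len(max_retries)) {
    dup <- duplicated(bc)
    if (!any(dup)) return(bc)
    bc[dup] <- random_dna(sum(dup), width)
  }
  stop("could not generate ", n, " unique barcodes of length ", width,
       " after ", max_retries, " retries")
}

# structural checks on an enhancer library manifest
validate_library <- function(library) {
  stopifnot(is.data.frame(library),
            all(c("enhancer_id", "class", "barcode") %in% names(library)))
  if (nrow(library) == 0) return(invisible(library))
  if (anyDuplicated(library$barcode)) stop("library barcodes are not unique")
  if (!all(library$class %in% ENHANCER_CLASSES)) {
    stop("library classes must be one of: ",
         paste(ENHANCER_CLASSES, collapse = ", "))
  }
  if (length(unique(nchar(library$barcode))) != 1) {
    stop("library barcodes must all have the same length")
  }
  invisible(library)
}

#' Describe the amplicon read layout
#'
#' The amplicon design places a constant priming site (the anchor) between
#' the enhancer and its barcode; the barcode starts `barcode_offset` bases
#' after the anchor ends (0-based, half-open coordinates). Reads may carry
#' the construct on the reverse-complement strand.
#'
#' @param anchor Constant anchor sequence (A/C/G/T, length >= 8).
#' @param barcode_offset Bases between anchor end and barcode start (>= 0).
#' @param barcode_length Barcode length; must match the library.
#' @param orientation `"forward"` or `"reverse_complement"`.
#' @return An object of class `amplicon_layout`.
#' @export
amplicon_layout <- function(anchor = "TCGTCGGCAGCGTCAG", barcode_offset = 0L,
                            barcode_length = 16L,
                            orientation = c("forward", "reverse_complement")) {
  orientation <- match.arg(orientation)
  anchor <- toupper(anchor)
  if (nchar(anchor) < 8) stop("anchor must be at least 8 bases")
  if (!grepl("^[ACGT]+$", anchor)) stop("anchor must contain only A/C/G/T")
  stopifnot(barcode_offset >= 0, barcode_length > 0)
  structure(list(anchor = anchor,
                 barcode_offset = as.integer(barcode_offset),
                 barcode_length = as.integer(barcode_length),
                 orientation = orientation),
            class = "amplicon_layout")
}

#' Programmed ground truth for a simulated reporter library
#'
#' Assigns every library entry a DNA frequency (log-normal across entries,
#' renormalized to sum to one, mimicking realistic library skew) and a
#' programmed RNA:DNA activity. Activities are drawn log-normally within
#' each class and then rescaled so that each class mean equals its
#' programmed value exactly; the default programs a 4.5-fold
#' cardiomyocyte:endothelial class-mean ratio with inactive controls.
#'
#' @param library An enhancer library from [make_library()].
#' @param class_mean_activity Named vector of programmed class mean
#'   activities.
#' @param activity_log_sd Log-scale SD of within-class activity spread.
#' @param dna_log_sd Log-scale SD of library representation skew.
#' @param seed Integer seed.
#' @return A tibble (class `ground_truth`) with `enhancer_id`, `barcode`,
#'   `class`, `activity` and `dna_frequency`; the seed is kept as an
#'   attribute.
#' @export
make_ground_truth <- function(library,
                              class_mean_activity = c(cardiomyocyte = 4.5,
                                                      endothelial = 1,
                                                      esc = 1),
                              activity_log_sd = 0.4, dna_log_sd = 0.5, seed) {
  validate_library(library)
  stopifnot(all(library$class %in% names(class_mean_activity)),
            all(class_mean_activity > 0))
  n <- nrow(library)
  out <- withr::with_seed(as.integer(seed), {
    act <- rlnorm(n, meanlog = 0, sdlog = activity_log_sd)
    for (cl in unique(library$class)) {
      i <- library$class == cl
      act[i] <- act[i] * class_mean_activity[[cl]] / mean(act[i])
    }
    fr <- rlnorm(n, meanlog = 0, sdlog = dna_log_sd)
    tibble::tibble(enhancer_id = library$enhancer_id,
                   barcode = library$barcode,
                   class = library$class,
                   activity = act,
                   dna_frequency = fr / sum(fr))
  })
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("ground_truth", class(out))
  out
}
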