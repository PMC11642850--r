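#' @importFrom stats coef lm median quantile rnorm rmultinom rlnorm runmed
#'   residuals sd cor aov TukeyHSD t.test
#' @importFrom utils read.csv write.csv read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Derive a child seed from a master seed
#'
#' Child seeds are produced by a fixed affine counter scheme,
#' `(seed + 1000003 * index) mod (2^31 - 1)`, so that any subset of a
#' simulation (one sample, one cell) is independently reproducible from the
#' master seed and its index. Results stay within 32-bit integer range.
#'
#' @param seed Integer master seed.
#' @param index Nonnegative integer counter.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(index))
  as.integer((as.numeric(seed) + 1000003 * as.numeric(index)) %% 2147483647)
}

# n random DNA strings of the given width (vectorized paste over columns)
random_dna <- function(n, width) {
  if (n == 0) return(character(0))
  m <- matrix(sample(DNA_BASES, n * width, replace = TRUE), nrow = n)
  do.call(paste0, lapply(seq_len(width), function(j) m[, j, drop = TRUE]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
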