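test_that("extract_barcodes matches a brute-force count on toy reads", {
  lay <- toy_layout(barcode_length = 6, offset = 2)
  lib <- tibble::tibble(enhancer_id = c("E1", "E2", "E3"),
                        class = c("cardiomyocyte", "endothelial", "esc"),
                        barcode = c("AAAAAA", "CCCCCC", "GGGGGG"))
  reads <- c(rep(toy_read("AAAAAA", lay), 4),
             rep(toy_read("CCCCCC", lay), 3),
             rep(toy_read("GGGGGG", lay), 2),
             "TTTTTTTTTTTTTTTTTTTT")  # junk, no anchor
  ct <- extract_barcodes(reads, lib, lay)

  # independent brute-force oracle: scan each read by hand
  oracle <- c(AAAAAA = 0L, CCCCCC = 0L, GGGGGG = 0L)
  junk <- 0L
  for (r in reads) {
    hit <- regexpr(lay$anchor, r, fixed = TRUE)
    if (hit < 0) { junk <- junk + 1L; next }
    bc <- substr(r, hit + nchar(lay$anchor) + 2, hit + nchar(lay$anchor) + 7)
    if (bc %in% names(oracle)) oracle[bc] <- oracle[bc] + 1L
  }
  expect_equal(unname(ct$counts[, 1]), unname(oracle))
  expect_equal(unname(ct$counts[, 1]), c(4L, 3L, 2L))
  expect_equal(ct$discarded$no_anchor, junk)
  expect_equal(ct$discarded$unmatched_barcode, 0L)
})

test_that("extract_barcodes handles whitelist misses, truncation and rc", {
  lay <- toy_layout(barcode_length = 6)
  lib <- tibble::tibble(enhancer_id = "E1", class = "cardiomyocyte",
                        barcode = "AAAAAA")
  # valid layout but a different barcode -> unmatched
  ct <- extract_barcodes(rep(toy_read("CCCCCC", lay), 5), lib, lay)
  expect_equal(sum(ct$counts), 0L)
  expect_equal(ct$discarded$unmatched_barcode, 5L)
  # barcode window past the read end -> its own discard tally
  short <- paste0("GG", lay$anchor, "AAA")
  ct2 <- extract_barcodes(short, lib, lay)
  expect_equal(ct2$discarded$barcode_truncated, 1L)
  # reverse-complement orientation round-trips through the simulator
  lib2 <- toy_library()
  tr <- make_ground_truth(lib2, seed = 61)
  lay_rc <- toy_layout(orientation = "reverse_complement")
  sim <- simulate_reads(lib2, tr, lay_rc, 1000, 1000)
  ct3 <- extract_barcodes(list(RNA = sim$rna, DNA = sim$dna), lib2, lay_rc)
  expect_equal(unname(colSums(ct3$counts)), c(1000L, 1000L))
  # empty read stream is an empty table, not an error
  ct4 <- extract_barcodes(character(0), lib2, toy_layout())
  expect_equal(sum(ct4$counts), 0L)
  expect_equal(sum(unlist(ct4$discarded[, -1])), 0L)
})

test_that("reads are conserved across matched and discarded tallies", {
  lib <- toy_library()
  tr <- make_ground_truth(lib, seed = 71)
  lay <- toy_layout()
  sim <- simulate_reads(lib, tr, lay, 5000, 5000, anchorless_fraction = 0.07)
  ct <- extract_barcodes(list(RNA = sim$rna, DNA = sim$dna), lib, lay)
  matched <- colSums(ct$counts)
  discarded <- rowSums(as.matrix(ct$discarded[, -1]))
  expect_equal(unname(matched + discarded), unname(ct$total_reads))
  expect_equal(unname(ct$total_reads), c(5000L, 5000L))
  # with no junk reads there are no discards at all
  clean <- simulate_reads(lib, tr, lay, 2000, 2000)
  ctc <- extract_barcodes(list(RNA = clean$rna, DNA = clean$dna), lib, lay)
  expect_equal(sum(unlist(ctc$discarded[, -1])), 0L)
})

test_that("counts_to_rpm is depth normalization to one million", {
  m <- matrix(c(2L, 3L, 5L), dimnames = list(c("A", "B", "C"), "s1"))
  expect_equal(unname(counts_to_rpm(m)[, 1]), c(2e5, 3e5, 5e5))
  expect_equal(unname(counts_to_rpm(matrix(7L, dimnames =
                                             list("A", "s")))[, 1]), 1e6)
  expect_error(counts_to_rpm(matrix(c(1L, 0L), ncol = 2,
                                    dimnames = list("A", c("s1", "s2")))),
               "s2")
  # column sums are exactly 1e6 (relative tolerance 1e-6)
  set.seed(81)
  big <- matrix(rpois(300, 50), ncol = 3,
                dimnames = list(NULL, paste0("s", 1:3)))
  expect_equal(unname(colSums(counts_to_rpm(big))), rep(1e6, 3),
               tolerance = 1e-6)
})

test_that("RPM of a multinomial sample tracks the true frequencies", {
  p <- c(0.5, 0.3, 0.15, 0.05)
  depth <- 1e6
  set.seed(91)
  counts <- matrix(rmultinom(1, depth, p), dimnames = list(letters[1:4], "s"))
  rpm <- counts_to_rpm(counts)[, 1]
  sd3 <- 3 * sqrt(depth * p * (1 - p)) / depth * 1e6  # binomial SD in RPM
  expect_true(all(abs(rpm - p * 1e6) <= sd3))
})

test_that("compute_activity averages replicates then takes the ratio", {
  lib <- tibble::tibble(enhancer_id = "E1", class = "cardiomyocyte",
                        barcode = "AAAAAA")
  rna <- matrix(c(15000, 25000), 1, dimnames = list("AAAAAA", c("r1", "r2")))
  dna <- matrix(10000, 1, dimnames = list("AAAAAA", "d1"))
  act <- compute_activity(rna, dna, lib)
  expect_equal(act$activity, 2)  # mean(15k, 25k)/10k
  # identity when RNA == DNA
  act2 <- compute_activity(dna, dna, lib)
  expect_equal(act2$activity, 1)
  # zero DNA with zero pseudocount is flagged, not infinite
  dna0 <- matrix(0, 1, dimnames = list("AAAAAA", "d1"))
  act3 <- compute_activity(rna, dna0, lib)
  expect_equal(act3$flags, "zero_dna")
  expect_true(is.na(act3$activity))
  # with a pseudocount the row is usable and flagged pseudocounted
  act4 <- compute_activity(rna, dna0, lib, pseudocount_rpm = 1)
  expect_equal(act4$activity, (20000 + 1) / 1)
  expect_equal(act4$flags, "pseudocounted")
  # disjoint indices fail loudly
  rna_x <- matrix(1, 1, dimnames = list("CCCCCC", "r1"))
  expect_error(compute_activity(rna_x, dna, lib), "share no")
})

test_that("activity is invariant to per-sample scaling and monotone in counts", {
  lib <- toy_library()
  tr <- make_ground_truth(lib, seed = 101)
  lay <- toy_layout()
  sim <- simulate_reads(lib, tr, lay, 20000, 20000)
  ct <- extract_barcodes(list(RNA_1 = sim$rna, DNA_1 = sim$dna), lib, lay)
  base <- quick_activity(ct$counts, lib)
  scaled <- ct$counts
  scaled[, "RNA_1"] <- scaled[, "RNA_1"] * 7L
  expect_equal(quick_activity(scaled, lib)$activity, base$activity,
               tolerance = 1e-12)
  # bump one barcode's RNA count: its activity rises, all others fall
  bumped <- ct$counts
  bumped[1, "RNA_1"] <- bumped[1, "RNA_1"] + 500L
  after <- quick_activity(bumped, lib)
  expect_gt(after$activity[after$barcode == rownames(ct$counts)[1]],
            base$activity[base$barcode == rownames(ct$counts)[1]])
  others <- after$barcode != rownames(ct$counts)[1]
  expect_true(all(after$activity[others] < base$activity[others]))
})

test_that("normalize_activity pins the reference mean to one", {
  tbl <- tibble::tibble(
    enhancer_id = c("C1", "E1", "E2"),
    class = c("cardiomyocyte", "endothelial", "endothelial"),
    barcode = c("A", "B", "C"),
    activity = c(4, 2, 2), normalized_activity = NA_real_, flags = "")
  out <- normalize_activity(tbl)
  expect_equal(unname(attr(out, "adjustment_factors")), 0.5)
  expect_equal(out$normalized_activity, c(2, 1, 1))
  # reference already averaging one -> factor 1
  tbl$activity <- c(4, 0.5, 1.5)
  expect_equal(normalize_activity(tbl)$normalized_activity, tbl$activity)
  # missing reference rows fail loudly
  solo <- tbl[tbl$class == "cardiomyocyte", ]
  expect_error(normalize_activity(solo), "endothelial")
})

test_that("normalization is exact, ratio-preserving, per-stratum and idempotent", {
  set.seed(111)
  tbl <- tibble::tibble(
    enhancer_id = paste0("E", 1:40),
    class = sample(c("cardiomyocyte", "endothelial"), 40, replace = TRUE,
                   prob = c(0.5, 0.5)),
    promoter_id = rep(c("Mlc2v", "Tnni1"), each = 20),
    barcode = paste0("B", 1:40),
    activity = rlnorm(40, 0, 1), normalized_activity = NA_real_, flags = "")
  # ensure both strata have reference rows
  tbl$class[c(1, 21)] <- "endothelial"
  out <- normalize_activity(tbl)
  for (p in c("Mlc2v", "Tnni1")) {
    i <- out$promoter_id == p
    expect_equal(mean(out$normalized_activity[i & out$class == "endothelial"]),
                 1, tolerance = 1e-9)
    # within-stratum ratios preserved
    r_old <- tbl$activity[i] / tbl$activity[i][1]
    r_new <- out$normalized_activity[i] / out$normalized_activity[i][1]
    expect_equal(r_new, r_old, tolerance = 1e-12)
  }
  expect_equal(normalize_activity(out)$normalized_activity,
               out$normalized_activity)
})

test_that("episomal DNA filter is a strict > threshold over all replicates", {
  cpm <- rbind(kept = c(31, 40, 35),
               low_one = c(31, 29, 40),
               at_threshold = c(30, 30, 30))
  keep <- filter_episomal(cpm, min_cpm = 30)
  expect_equal(unname(keep), c(TRUE, FALSE, FALSE), ignore_attr = TRUE)
  expect_identical(attr(keep, "keep"), "kept")
})

test_that("replicate_correlation matches a brute-force Pearson", {
  v <- c(0.5, 0.3, 0.2)
  expect_equal(replicate_correlation(v, v), 1)
  # exact negation about the mean: r = -1, r^2 = 1
  expect_equal(replicate_correlation(v, 2 * mean(v) - v), 1)
  expect_warning(r <- replicate_correlation(c(1, 1, 1), v), "variance")
  expect_true(is.na(r))
  # two multinomial draws vs an independent Pearson implementation
  set.seed(121)
  p <- rlnorm(50); p <- p / sum(p)
  a <- rmultinom(1, 1e6, p)[, 1] / 1e6
  b <- rmultinom(1, 1e6, p)[, 1] / 1e6
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  expect_equal(replicate_correlation(a, b), (num / den)^2,
               tolerance = 1e-12)
  expect_gt(replicate_correlation(a, b), 0.8)
})

test_that("group_fold_change is the ratio of class means", {
  tbl <- tibble::tibble(
    enhancer_id = paste0("E", 1:4),
    class = c("cardiomyocyte", "cardiomyocyte", "endothelial", "endothelial"),
    barcode = paste0("B", 1:4),
    activity = c(2, 4, 1, 1), normalized_activity = NA_real_, flags = "")
  expect_equal(group_fold_change(tbl), 3)
  tbl$activity <- c(1.5, 1.5, 1.5, 1.5)
  expect_equal(group_fold_change(tbl), 1)
  expect_error(group_fold_change(tbl, class_a = "esc"), "esc")
})

test_that("compare_assays recovers identity and linear relations", {
  tbl <- tibble::tibble(
    enhancer_id = paste0("E", 1:6),
    class = "cardiomyocyte", barcode = paste0("B", 1:6),
    activity = c(0.2, 0.6, 1.1, 2.3, 3.0, 4.4),
    normalized_activity = NA_real_, flags = "")
  same <- compare_assays(tbl, tbl)
  expect_equal(same$r_squared, 1)
  expect_equal(same$slope, 1)
  expect_equal(same$intercept, 0, tolerance = 1e-12)
  doubled <- tbl
  doubled$activity <- 2 * tbl$activity
  expect_equal(compare_assays(tbl, doubled)$slope, 2)
  # uncorrelated tables: r^2 equals a direct Pearson on the joined rows
  set.seed(131)
  other <- tbl
  other$activity <- rlnorm(6)
  cmp <- compare_assays(tbl, other)
  expect_equal(cmp$r_squared, cor(tbl$activity, other$activity)^2,
               tolerance = 1e-12)
  expect_error(compare_assays(tbl[1:2, ], tbl[1:2, ]), "fewer than 3")
})

test_that("count tables round-trip through TSV", {
  m <- matrix(c(5L, 0L, 2L, 9L), 2,
              dimnames = list(c("AAAA", "CCCC"), c("RNA_1", "DNA_1")))
  path <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(barcode = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(read_count_tsv(path), m)
})
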