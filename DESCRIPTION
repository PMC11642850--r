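Package: mpracal
Title: Quantification of Integrated and Episomal Reporter Assays and
    Cardiomyocyte Calcium Transient Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying barcoded massively parallel reporter
    assays (MPRAs) in which candidate enhancers are either genomically
    integrated into a native gene's 3' UTR or carried episomally: barcode
    extraction from amplicon sequencing reads, reads-per-million
    normalization, RNA:DNA activity ratios, reference-class activity
    normalization, depth filters, replicate correlation and cross-assay
    comparison. Also implements an analysis pipeline for paced
    cardiomyocyte calcium transients: photobleach removal, median
    filtering, baseline normalization, peak detection, per-beat transient
    metrics (amplitude, upstroke/downstroke velocity, time to 50% decay),
    low-peak anomaly classification and a best-fit-line peak-amplitude
    variation statistic for detecting alternans-like phenotypes. Seeded
    synthetic-data generators for barcoded enhancer libraries, amplicon
    reads and paced fluorescence traces make every stage testable against
    known ground truth, and group-comparison statistics (Dunnett, Tukey,
    Student's t) are provided for reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    multcomp,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
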