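# mpracal

Quantification of barcoded massively parallel reporter assays (MPRAs) and
analysis of paced cardiomyocyte calcium transients, with seeded
synthetic-data generators for both.

## What it is for

Two recurring computational tasks in cardiac functional genomics:

**1. Reporter-assay quantification.** A pool of candidate enhancers —
e.g. 25 cardiomyocyte enhancers, 25 negative-control endothelial/endocardial
enhancers and 5 ESC-bound control regions — is tagged with unique barcodes
and read out by amplicon sequencing of RNA and DNA, either genomically
integrated into a native gene's 3' UTR (STARR-seq-style) or on an episomal
vector under minimal promoters. The package extracts barcodes from reads
(anchor search → whitelist match, with full discard accounting), normalizes
to reads per million, and computes per-element activity

    activity_b = RPM_RNA(b) / RPM_DNA(b)

with replicate averaging before the ratio, a configurable pseudocount, and
a per-stratum normalization that rescales activities so the
negative-control class mean equals 1. It also provides the strict
`>30 CPM in all DNA replicates` episomal filter, replicate r², class-mean
fold changes, and cross-assay comparison (r², OLS fit).

**2. Calcium-transient analysis.** Per-cell fluorescence traces from paced
recordings (2 Hz, last 5 cycles) are admitted by QC (≥5 full cycles, finite
values), photobleach-corrected, median-filtered and normalized to ΔF/F₀;
peaks are detected and summarized per beat (amplitude, maximal
upstroke/downstroke velocity, time from peak to 50% decay). Anomalies are
classified by the low-peak rule (a peak at 10–94% of the cell's reference
height is "low"; ≥3 low peaks flag the cell) and by a peak-amplitude
variation statistic: an OLS best-fit line through the peak coordinates,
each peak's distance to the line normalized to peak height, averaged per
cell. Beat-to-beat alternans produces large scores; regular cells score
near zero.

Group-comparison statistics used in reporting (Dunnett many-to-one, one-way
ANOVA + Tukey HSD, Student's/Welch's t) are included as tested wrappers.

## Worked example

```r
library(mpracal)

# --- simulate an integrated MPRA with a programmed 4.5-fold class ratio ---
lib    <- make_library(n_cm = 25, n_endo = 25, n_esc = 5,
                       barcode_length = 16, seed = 101)
truth  <- make_ground_truth(lib, seed = 102)   # CM:endothelial mean = 4.5
layout <- amplicon_layout()
sim    <- simulate_reads(lib, truth, layout, depth_rna = 2e5,
                         depth_dna = 2e5, anchorless_fraction = 0.02)

counts <- extract_barcodes(list(RNA_1 = sim$rna, DNA_1 = sim$dna),
                           lib, layout)
counts$discarded
#>   sample_id no_anchor barcode_truncated unmatched_barcode
#> 1 RNA_1          4000                 0                 0
#> 2 DNA_1          4000                 0                 0

rna <- counts_to_rpm(counts$counts[, "RNA_1", drop = FALSE])
dna <- counts_to_rpm(counts$counts[, "DNA_1", drop = FALSE])
activity <- normalize_activity(compute_activity(rna, dna, lib))
group_fold_change(activity)
#> [1] 4.496575
```

The 4,000 discards per sample are the 2% simulated anchor-free junk reads;
the recovered cardiomyocyte:endothelial fold change matches the programmed
4.5 within multinomial sampling error at this depth.

```r
# --- calcium: a control group vs an alternans group ---
specs <- list(control   = trace_spec(alternans_ratio = 1,   seed = 1),
              alternans = trace_spec(alternans_ratio = 0.6,
                                     alternans_phase = NA,  seed = 1))
pop <- simulate_cell_population(25, specs, seed = 9, jitter_cv = 0.05)
res <- analyze_population(pop)
res$groups[, c("group", "n_cells", "t50", "multi_low_fraction",
               "variation_score")]
#>   group     n_cells   t50 multi_low_fraction variation_score
#> 1 alternans      25 0.118               0.72          0.264
#> 2 control        25 0.118               0.28          0.0120
```

Alternating beats leave the transient kinetics (t50) untouched but drive
the variation score more than an order of magnitude above control and raise
the fraction of cells with three or more low peaks.

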