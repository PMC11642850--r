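---
title: "Methods: reporter-assay quantification and calcium transient analysis"
author: "mpracal authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reporter-assay quantification and calcium transient analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`mpracal` implements two analysis pipelines that are often needed together
in cardiac functional-genomics studies, plus the synthetic-data generators
that make both testable without access to raw sequencing or imaging data:

1. **Barcoded reporter-assay (MPRA/STARR-seq) quantification** — from
   amplicon reads to per-enhancer activities, for libraries that are either
   genomically integrated into a native gene's 3' UTR or carried on an
   episomal vector under an assortment of minimal promoters.
2. **Paced cardiomyocyte calcium-transient analysis** — from raw
   fluorescence traces to per-beat transient metrics, low-peak anomaly
   classification and a peak-amplitude variation statistic sensitive to
   alternans-like beat-to-beat alternation.

Group-comparison statistics used in reporting (Dunnett many-to-one, one-way
ANOVA with Tukey's HSD, Student's t) are thin, tested wrappers around
standard implementations (`multcomp`, `stats`).

## Reporter-assay model

Each library element (an enhancer, or a promoter–enhancer pair in episomal
mode) carries a unique DNA barcode downstream of a constant priming site
(the *anchor*). Sequencing the barcoded amplicon from RNA and from DNA
gives, after whitelist matching, a count table $k_{bs}$ (barcode $b$,
sample $s$). The quantities computed are:

* **Depth normalization**: $\mathrm{RPM}_{bs} = 10^6\, k_{bs} / \sum_b k_{bs}$
  (identically CPM). Column totals use matched reads only; discarded reads
  (no anchor, barcode window past the read end, off-whitelist barcode) are
  tallied per sample so that matched + discarded equals reads processed.
* **Activity**: replicate RPM columns are averaged within each analyte
  first, then
  $a_b = (\overline{\mathrm{RPM}}^{\mathrm{RNA}}_b + c) /
         (\overline{\mathrm{RPM}}^{\mathrm{DNA}}_b + c)$
  with pseudocount $c$ (default 0; zero-DNA rows are flagged and excluded
  rather than infinite). Averaging frequencies before the ratio is stabler
  at low counts than averaging per-replicate ratios.
* **Normalized activity**: within each stratum (each promoter in episomal
  mode; the whole table otherwise) all activities are multiplied by one
  scalar chosen so the negative-control (endothelial) class mean equals 1.
  A single shared factor preserves every within-stratum activity ratio and
  makes the operation idempotent.
* **Episomal depth filter**: a pair is kept only when its DNA abundance is
  strictly above 30 CPM in *every* DNA replicate.
* **Summaries**: squared Pearson correlation between replicate frequency
  vectors; class-mean fold change
  $\mathrm{mean}(a_{\mathrm{CM}})/\mathrm{mean}(a_{\mathrm{endo}})$; and a
  cross-assay comparison (inner join on element, $r^2$ and an OLS fit).

**Identifiability.** Because RNA frequencies are renormalized to a simplex,
the frequency-ratio activity is identified only up to the constant
$\sum_b p_b a_b$ (DNA frequency times true activity, summed). All
reported quantities — normalized activities, class fold changes,
correlations — are invariant to this constant; absolute activities from the
simulator are recovered up to it exactly.

### Barcode extraction conventions

* Anchor search is an exact substring match by default; a one-mismatch mode
  (via `Biostrings::vmatchPattern`) is available behind `max_mismatch = 1`.
* If a read contains the anchor twice, the first occurrence is used.
* All offsets are 0-based, half-open; the barcode starts `barcode_offset`
  bases after the anchor ends.
* `orientation = "reverse_complement"` reverse-complements reads before the
  search; mixed orientations are not auto-detected.

## Calcium-transient model

A trace is the mean fluorescence of one segmented, paced cell over time
(uniform sampling). The per-cell pipeline is:

1. **QC admission** (`qc_admit`): cells whose recording stops before
   `min_cycles` (default 5) full pacing cycles, or that contain non-finite
   samples, are excluded with a reason. Exclusion is a result, not an
   error.
2. **Preprocessing** (`preprocess`): (i) photobleaching is removed by
   fitting a linear (default) or exponential trend to per-cycle diastolic
   baseline points — the minimum of the median-smoothed trace within each
   pacing cycle — and dividing it out; (ii) a running median filter
   (default 5 samples) suppresses impulsive noise; (iii) the trace is
   rescaled to $\Delta F/F_0 = F/F_0 - 1$ using the median of the per-cycle
   minima as $F_0$, so the diastolic baseline sits at 0.
3. **Peak detection** (`detect_peaks`): local maxima above a prominence
   threshold (default 20% of the cell's maximum $\Delta F/F_0$), thinned to
   a minimum separation (default 60% of the pacing period; taller peaks
   win ties).
4. **Per-beat metrics** (`transient_metrics`): beat windows run midpoint to
   midpoint between peaks. Amplitude is the peak height; maximal upstroke
   and downstroke velocities are the extrema of the first difference
   divided by the sampling interval; time to 50% decay (t50) is found by
   linear interpolation between the bracketing samples. Beats that never
   reach half height before the window ends are flagged and excluded from
   the t50 mean.
5. **Low-peak classification** (`classify_low_peaks`): a peak is *low* when
   its height is between 10% and 94% (inclusive endpoints) of the cell's
   reference height (default: the maximum peak; median optional). Three or
   more low peaks flag the cell as a multi-low-peak anomaly.
6. **Peak-amplitude variation** (`peak_variation`): an OLS line is fitted
   to the peak coordinates (height vs time); each peak's absolute distance
   from the line is normalized to its height; the per-cell score is the
   mean normalized deviation. The score is 0 exactly when heights are
   affine in time, and invariant to scaling all heights by a constant. The
   per-cell mean is this package's aggregation choice; the per-peak
   deviations are also returned for plotting.

Defaults in `calcium_config()` are stated in units of the recording
(seconds, fractions of the pacing period, fractions of the reference
height) so they transfer across sample rates.

## What the synthetic generators emulate

* **Library** (`make_library`): 25 cardiomyocyte + 25 endothelial + 5 ESC
  negative-control elements by default, with unique random barcodes
  (uniform over $\{A,C,G,T\}^L$, duplicate rejection with bounded retries;
  no minimum pairwise Hamming distance is enforced).
* **Ground truth** (`make_ground_truth`): log-normal library skew
  (renormalized DNA frequencies) and log-normal within-class activity
  spread rescaled so class means are *exactly* the programmed values
  (default cardiomyocyte:endothelial = 4.5, controls at 1). The rescaling
  makes end-to-end fold-change recovery a sharp test.
* **Reads** (`simulate_reads`): multinomial sampling at the requested
  depths; RNA frequencies proportional to DNA frequency × activity;
  optional dropout of elements (e.g. a failed synthesis); an exact
  `round(fraction × depth)` count of anchor-free junk reads; optional
  uniform per-base substitution errors (off by default). Flanking pads are
  drawn from a pool of random sequences. PCR amplification-bias chemistry
  is *not* modelled.
* **Traces** (`simulate_trace`): 2 Hz pacing, 5 recorded cycles, 100 Hz
  sampling by default. Each beat rises linearly over `upstroke_time`
  (default 50 ms) to `1 + amplitude` and decays exponentially with
  `decay_tau` (default 150 ms), chosen so t50 has the closed form
  $\tau \ln 2$. Additive linear (default) or exponential drift models
  photobleaching; Gaussian noise models shot/readout noise. Cell
  segmentation, motion and indicator kinetics are *not* modelled, so
  passing tests demonstrate correctness of the computations, not robustness
  to every feature of real recordings.
* **Alternans** (`alternans_ratio < 1`): every second beat is scaled. With
  five recorded cycles, a recording that starts on a large beat shows two
  small peaks and one that starts on a small beat shows three — so the
  phase of the alternation relative to recording onset, which is arbitrary
  in a real experiment, decides whether the ≥3-low-peak flag can fire.
  `alternans_phase` makes the phase explicit (0 large-first, 1 small-first)
  and `NA` randomizes it per cell in `simulate_cell_population`, which is
  the realistic population behaviour.

**Seeding.** Every generator is bit-reproducible for a fixed seed. Child
seeds (per sample, per cell) derive from the master seed by the documented
counter scheme `(seed + 1000003·k) mod (2^31 − 1)` (`derive_seed`), so any
subset of a simulation is independently reproducible.

## Numerical choices and degenerate inputs

* Strict `>` in the episomal CPM filter; inclusive endpoints in the
  10–94% low-peak band.
* Peak thinning keeps the taller of two close peaks (greedy by height).
* t50 crossings are linearly interpolated between bracketing samples.
* Zero-variance inputs to the replicate correlation return `NA` with a
  warning rather than an error; an all-zero count column, a missing
  reference class, or an all-rejected group are explicit failures naming
  the offender.
* A zero-DNA barcode with zero pseudocount is flagged and excluded, never
  infinite.
* `peak_variation` on fewer than three peaks returns a reasoned
  not-a-value (a line through two points has zero residual).

## Known limitations

* With the default 5-sample median filter the per-cycle minimum used for
  $F_0$ is slightly contaminated by the decay tail of the previous beat,
  biasing absolute $\Delta F/F_0$ amplitude downward by roughly 10–15% at
  100 Hz with $\tau = 0.15$ s. All ratio-based quantities (low-peak
  counts, normalized deviations, t50) are unaffected; analyses that need
  unbiased absolute amplitudes should raise the sampling rate or reduce
  the filter window.
* Dividing out an *additive* drift estimate rescales the transient by the
  local trend value; for drift magnitudes typical of photobleaching over a
  2.5 s recording (a few percent) the distortion is below the noise floor.
* The statistics wrappers assume the usual one-way ANOVA conditions
  (independence, normality, equal variances for the classical forms);
  Welch's t is available behind a flag.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script exercise the full pipelines at
desk scale: one million reads per analyte for fold-change recovery
(recovering the programmed 4.5-fold cardiomyocyte:endothelial class-mean
ratio within 10%), 50 cells per group for the alternans power comparison,
and 1000 seeded null repetitions for type-I-error calibration of the
Dunnett/Tukey/t wrappers (nominal 5% within ±1.5 percentage points). These
sizes were chosen so each property is measured well inside its sampling
error while the whole suite runs in about a minute.
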