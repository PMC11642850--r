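#' Quality-control admission of a recorded trace
#'
#' A cell is excluded when the recording terminated before the required
#' number of full pacing cycles (within one sample interval of slack) or
#' when the trace contains non-finite values. Rejection is a result, not an
#' error.
#'
#' @param trace A [calcium_trace()].
#' @param min_cycles Minimum number of full cycles (default 5).
#' @return A list with `admitted` (logical) and `reason` (`NA`,
#'   `"short_recording"` or `"non_finite"`).
#' @export
qc_admit <- function(trace, min_cycles = 5) {
  stopifnot(inherits(trace, "calcium_trace"))
  if (any(!is.finite(trace$intensity))) {
    return(list(admitted = FALSE, reason = "non_finite"))
  }
  needed <- min_cycles / trace$pacing_hz
  if (trace_duration(trace) < needed - trace_dt(trace)) {
    return(list(admitted = FALSE, reason = "short_recording"))
  }
  list(admitted = TRUE, reason = NA_character_)
}

#' Preprocess a raw fluorescence trace to dF/F0
#'
#' Three deterministic steps: (1) the photobleaching trend is estimated
#' from per-cycle diastolic baseline points (the minimum of the
#' median-smoothed trace within each pacing cycle), fitted as a linear or
#' exponential function of time, and divided out; (2) a running median
#' filter of `median_window` samples suppresses impulsive noise; (3) the
#' diastolic baseline F0 (median of the per-cycle minima of the filtered
#' trace) is used to rescale the trace to `F/F0 - 1`, so the baseline sits
#' at 0 and values are dF/F0.
#'
#' @param trace A [calcium_trace()] (raw fluorescence).
#' @param median_window Odd window width in samples (1 disables filtering).
#' @param detrend `"linear"` (default), `"exponential"` or `"none"`.
#' @return A [calcium_trace()] in dF/F0 units.
#' @export
preprocess <- function(trace, median_window = 5,
                       detrend = c("linear", "exponential", "none")) {
  stopifnot(inherits(trace, "calcium_trace"))
  detrend <- match.arg(detrend)
  n <- length(trace$intensity)
  if (median_window < 1 || median_window %% 2 == 0) {
    stop("median_window must be a positive odd integer")
  }
  if (median_window >= n) stop("median_window must be below trace length")
  x <- trace$intensity
  t <- trace$time
  win <- cycle_windows(trace)

  # diastolic anchor points: per-cycle minimum of the smoothed raw trace
  sm <- smooth_median(x, median_window)
  base_t <- base_v <- numeric(length(win))
  for (k in seq_along(win)) {
    j <- win[[k]][which.min(sm[win[[k]]])]
    base_t[k] <- t[j]
    base_v[k] <- sm[j]
  }
  trend <- rep(1, n)
  if (detrend != "none" && length(win) >= 2) {
    if (detrend == "linear") {
      fit <- lm(base_v ~ base_t)
      trend <- coef(fit)[1] + coef(fit)[2] * t
    } else {
      if (any(base_v <= 0)) stop("exponential detrend needs positive baseline")
      fit <- lm(log(base_v) ~ base_t)
      trend <- exp(coef(fit)[1] + coef(fit)[2] * t)
    }
    if (any(trend <= 0)) stop("fitted photobleach trend is non-positive")
    x <- x / trend
  }
  x <- smooth_median(x, median_window)
  mins <- vapply(win, function(i) min(x[i]), numeric(1))
  f0 <- median(mins)
  if (!is.finite(f0) || f0 <= 0) stop("degenerate baseline estimate")
  calcium_trace(t, x / f0 - 1, trace$pacing_hz, trace$cell_id, trace$group)
}

# running median with median endrule; window 1 is the identity
smooth_median <- function(x, window) {
  if (window <= 1) x else as.numeric(runmed(x, window, endrule = "median"))
}

# sample indices of each pacing cycle
cycle_windows <- function(trace) {
  period <- 1 / trace$pacing_hz
  k <- pmax(0, floor((trace$time + 1e-12) / period))
  split(seq_along(k), k)
}

#' Detect transient peaks in a preprocessed trace
#'
#' Local maxima whose height (baseline is 0 after [preprocess()]) reaches
#' `min_prominence`, thinned so that retained peaks are at least
#' `min_separation` apart (taller peaks win).
#'
#' @param trace Preprocessed [calcium_trace()] (dF/F0 units).
#' @param min_prominence Minimum peak height; default 20% of the trace
#'   maximum.
#' @param min_separation Minimum peak spacing in seconds; default 60% of
#'   the pacing period. Must be below one pacing period.
#' @return An object of class `peak_set` with `t`, `height` and
#'   `baseline_value` (0).
#' @export
detect_peaks <- function(trace, min_prominence = NULL,
                         min_separation = NULL) {
  stopifnot(inherits(trace, "calcium_trace"))
  x <- trace$intensity
  if (is.null(min_prominence)) min_prominence <- 0.2 * max(x)
  if (is.null(min_separation)) {
    min_separation <- 0.6 / trace$pacing_hz
  }
  if (min_separation >= 1 / trace$pacing_hz) {
    stop("min_separation must be below one pacing period")
  }
  n <- length(x)
  cand <- which(x[-c(1, n)] > x[-c(n - 1, n)] &
                  x[-c(1, n)] >= x[-c(1, 2)]) + 1L
  cand <- cand[x[cand] >= min_prominence]
  keep <- integer(0)
  for (i in cand[order(x[cand], decreasing = TRUE)]) {
    if (all(abs(trace$time[i] - trace$time[keep]) >= min_separation)) {
      keep <- c(keep, i)
    }
  }
  keep <- sort(keep)
  structure(list(t = trace$time[keep], height = x[keep],
                 baseline_value = 0, index = keep),
            class = "peak_set")
}

#' Per-beat transient metrics
#'
#' Beat windows run from the midpoint after the previous peak to the
#' midpoint before the next (trace ends for the outer beats). Per beat:
#' amplitude is the peak height; maximal upstroke and downstroke velocities
#' are the extrema of the first difference divided by the sample interval
#' (downstroke reported as a magnitude); t50 is the linearly interpolated
#' time from the peak to the first crossing of half the peak height. Beats
#' whose decay never reaches 50% before the window ends are flagged and
#' excluded from the t50 mean.
#'
#' @param trace Preprocessed [calcium_trace()].
#' @param peaks [detect_peaks()] output for the same trace (>= 1 peak).
#' @return A list with `per_beat` (tibble: beat, t_peak, amplitude,
#'   max_upstroke, max_downstroke, t50, t50_defined) and `means`
#'   (per-cell averages; t50 over defined beats only).
#' @export
transient_metrics <- function(trace, peaks) {
  stopifnot(inherits(trace, "calcium_trace"), inherits(peaks, "peak_set"))
  np <- length(peaks$t)
  if (np == 0) stop("transient_metrics requires at least one peak")
  x <- trace$intensity
  t <- trace$time
  dt <- trace_dt(trace)
  idx <- peaks$index
  bounds <- c(1L,
              if (np > 1) round((idx[-np] + idx[-1]) / 2),
              length(x))
  rows <- vector("list", np)
  for (b in seq_len(np)) {
    lo <- bounds[b]
    hi <- bounds[b + 1]
    seg <- x[lo:hi]
    d <- diff(seg) / dt
    h <- peaks$height[b]
    p <- idx[b]
    t50 <- NA_real_
    after <- if (p < hi) seq(p + 1L, hi) else integer(0)
    cross <- after[x[after] <= h / 2]
    if (length(cross) > 0) {
      j <- cross[1]
      frac <- (x[j - 1] - h / 2) / (x[j - 1] - x[j])
      t50 <- (t[j - 1] + frac * dt) - t[p]
    }
    rows[[b]] <- tibble::tibble(beat = b, t_peak = peaks$t[b], amplitude = h,
                                max_upstroke = max(d),
                                max_downstroke = max(-d),
                                t50 = t50, t50_defined = !is.na(t50))
  }
  per_beat <- do.call(rbind, rows)
  means <- tibble::tibble(
    amplitude = mean(per_beat$amplitude),
    max_upstroke = mean(per_beat$max_upstroke),
    max_downstroke = mean(per_beat$max_downstroke),
    t50 = if (any(per_beat$t50_defined)) {
      mean(per_beat$t50[per_beat$t50_defined])
    } else NA_real_,
    n_beats = np)
  list(per_beat = per_beat, means = means)
}

#' Classify low peaks within a cell
#'
#' A peak is "low" when its height, as a fraction of the cell's reference
#' height, falls inside the low band (default 10--94%, endpoints
#' inclusive); peaks below the band floor are not counted as low. A cell
#' with three or more low peaks is flagged as a multi-low-peak anomaly.
#'
#' @param peaks A `peak_set` (>= 1 peak).
#' @param low_band Lower and upper fractions of the reference height.
#' @param reference `"max"` (default) or `"median"` peak height.
#' @return A list of class `anomaly_report`: `n_low_peaks`,
#'   `multi_low_flag`, `low_band`, `reference_height`, `peak_ratio`, `low`.
#' @export
classify_low_peaks <- function(peaks, low_band = c(0.10, 0.94),
                               reference = c("max", "median")) {
  stopifnot(inherits(peaks, "peak_set"), length(peaks$height) >= 1,
            length(low_band) == 2, low_band[1] < low_band[2])
  reference <- match.arg(reference)
  ref <- switch(reference, max = max(peaks$height),
                median = median(peaks$height))
  if (ref == 0) stop("reference peak height is zero")
  ratio <- peaks$height / ref
  low <- ratio >= low_band[1] & ratio <= low_band[2]
  structure(list(n_low_peaks = sum(low), multi_low_flag = sum(low) >= 3,
                 low_band = low_band, reference_height = ref,
                 peak_ratio = ratio, low = low),
            class = "anomaly_report")
}

#' Peak-amplitude variation statistic
#'
#' Fits an ordinary least-squares line to the peak coordinates (height vs
#' time), measures each peak's distance from the line, normalizes the
#' distance to the peak height, and summarizes the cell as the mean
#' normalized deviation. The score is zero exactly when the heights are an
#' affine function of peak time, and invariant to scaling all heights by a
#' constant.
#'
#' @param peaks A `peak_set` with at least 3 peaks (a line through two
#'   points has zero residual).
#' @return A list with `per_peak_deviation`, `variation_score` and, when
#'   undefined, a `reason`.
#' @export
peak_variation <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  if (length(peaks$t) < 3) {
    return(list(per_peak_deviation = NULL, variation_score = NA_real_,
                reason = "fewer_than_3_peaks"))
  }
  fit <- lm(height ~ t, data = list(height = peaks$height, t = peaks$t))
  dev <- abs(residuals(fit)) / peaks$height
  list(per_peak_deviation = unname(dev), variation_score = mean(dev),
       reason = NULL)
}

#' Default configuration for the per-cell calcium pipeline
#'
#' @param min_cycles QC minimum full cycles.
#' @param median_window Median filter width, samples.
#' @param detrend Photobleach model passed to [preprocess()].
#' @param min_prominence_frac Peak threshold as a fraction of the cell
#'   maximum dF/F0.
#' @param min_separation_frac Minimum peak spacing as a fraction of the
#'   pacing period.
#' @param low_band Low-peak band (fractions of reference height).
#' @param reference Low-peak reference height definition.
#' @return A named list of settings.
#' @export
calcium_config <- function(min_cycles = 5, median_window = 5,
                           detrend = "linear", min_prominence_frac = 0.2,
                           min_separation_frac = 0.6,
                           low_band = c(0.10, 0.94), reference = "max") {
  list(min_cycles = min_cycles, median_window = median_window,
       detrend = detrend, min_prominence_frac = min_prominence_frac,
       min_separation_frac = min_separation_frac, low_band = low_band,
       reference = reference)
}

#' Run the full calcium pipeline over a labelled population
#'
#' Applies QC admission, preprocessing, peak detection, per-beat metrics,
#' low-peak classification and the peak-variation statistic to every cell,
#' and summarizes by group.
#'
#' @param traces A `cell_population`, or a (named) list of
#'   [calcium_trace()]s carrying `cell_id`/`group` labels.
#' @param config Settings from [calcium_config()].
#' @return A list with `cells` (tidy per-cell tibble, rejected cells
#'   included with their reason) and `groups` (per-group summary:
#'   admitted n, metric means, multi-low fraction, mean variation score).
#' @export
analyze_population <- function(traces, config = calcium_config()) {
  if (inherits(traces, "cell_population")) traces <- traces$traces
  stopifnot(length(traces) >= 1)
  rows <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    row <- tibble::tibble(cell_id = tr$cell_id, group = tr$group,
                          admitted = FALSE, reject_reason = NA_character_,
                          n_peaks = NA_integer_, amplitude = NA_real_,
                          max_upstroke = NA_real_, max_downstroke = NA_real_,
                          t50 = NA_real_, n_low_peaks = NA_integer_,
                          multi_low_flag = NA,
                          variation_score = NA_real_)
    qc <- qc_admit(tr, config$min_cycles)
    if (!qc$admitted) {
      row$reject_reason <- qc$reason
      rows[[i]] <- row
      next
    }
    row$admitted <- TRUE
    pp <- preprocess(tr, config$median_window, config$detrend)
    pk <- detect_peaks(pp,
                       min_prominence =
                         config$min_prominence_frac * max(pp$intensity),
                       min_separation =
                         config$min_separation_frac / pp$pacing_hz)
    row$n_peaks <- length(pk$t)
    if (length(pk$t) >= 1) {
      tm <- transient_metrics(pp, pk)
      row$amplitude <- tm$means$amplitude
      row$max_upstroke <- tm$means$max_upstroke
      row$max_downstroke <- tm$means$max_downstroke
      row$t50 <- tm$means$t50
      an <- classify_low_peaks(pk, config$low_band, config$reference)
      row$n_low_peaks <- an$n_low_peaks
      row$multi_low_flag <- an$multi_low_flag
      row$variation_score <- peak_variation(pk)$variation_score
    }
    rows[[i]] <- row
  }
  cells <- do.call(rbind, rows)
  for (g in unique(cells$group)) {
    if (!any(cells$admitted[cells$group == g])) {
      stop("all cells of group '", g, "' were rejected")
    }
  }
  adm <- cells[cells$admitted, ]
  groups <- do.call(rbind, lapply(split(adm, adm$group), function(d) {
    tibble::tibble(group = d$group[1], n_cells = nrow(d),
                   amplitude = mean(d$amplitude, na.rm = TRUE),
                   max_upstroke = mean(d$max_upstroke, na.rm = TRUE),
                   max_downstroke = mean(d$max_downstroke, na.rm = TRUE),
                   t50 = mean(d$t50, na.rm = TRUE),
                   multi_low_fraction = mean(d$multi_low_flag, na.rm = TRUE),
                   variation_score = mean(d$variation_score, na.rm = TRUE))
  }))
  rownames(groups) <- NULL
  list(cells = cells, groups = groups)
}
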