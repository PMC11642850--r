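#' Specify a simulated paced calcium transient recording
#'
#' Defaults emulate a field-stimulated cardiomyocyte recording: 2 Hz pacing
#' with the last 5 cycles recorded, a fast linear upstroke followed by a
#' single-exponential decay (closed-form time to 50% decay of
#' `decay_tau * log(2)`), a slow additive photobleaching drift, and Gaussian
#' shot/readout noise. `alternans_ratio < 1` scales every second beat's
#' amplitude, producing the beat-to-beat alternation characteristic of
#' calcium alternans; `alternans_phase` selects whether the first recorded
#' beat is the large (0) or small (1) one, and `NA` lets
#' [simulate_cell_population()] randomize the phase per cell (the phase of
#' alternans relative to recording onset is arbitrary in a real recording).
#'
#' @param pacing_hz Pacing frequency in Hz (> 0).
#' @param n_cycles Number of recorded cycles (>= 1).
#' @param sample_rate Sampling rate in Hz (> 2 * pacing_hz).
#' @param amplitude Transient amplitude in dF/F0 units (baseline F0 = 1).
#' @param decay_tau Exponential decay time constant, seconds.
#' @param upstroke_time Linear upstroke duration, seconds.
#' @param drift_kind Photobleach drift model: `"linear"`, `"exponential"`
#'   or `"none"`.
#' @param drift_magnitude Drift rate per second (additive; negative for
#'   bleaching).
#' @param noise_sd SD of additive Gaussian noise, fluorescence units.
#' @param alternans_ratio Scale factor for every second beat, in `(0, 1]`
#'   (1 = no alternans).
#' @param alternans_phase 0, 1 or `NA` (randomize per cell).
#' @param seed Integer seed.
#' @return An object of class `trace_spec`.
#' @export
trace_spec <- function(pacing_hz = 2, n_cycles = 5, sample_rate = 100,
                       amplitude = 1, decay_tau = 0.15, upstroke_time = 0.05,
                       drift_kind = c("linear", "exponential", "none"),
                       drift_magnitude = -0.02, noise_sd = 0.02,
                       alternans_ratio = 1, alternans_phase = 0L, seed = 1L) {
  drift_kind <- match.arg(drift_kind)
  stopifnot(pacing_hz > 0, n_cycles >= 1, sample_rate > 2 * pacing_hz,
            amplitude >= 0, decay_tau > 0, upstroke_time > 0,
            noise_sd >= 0, alternans_ratio > 0, alternans_ratio <= 1,
            is.na(alternans_phase) || alternans_phase %in% c(0L, 1L))
  structure(list(pacing_hz = pacing_hz, n_cycles = as.integer(n_cycles),
                 sample_rate = sample_rate, amplitude = amplitude,
                 decay_tau = decay_tau, upstroke_time = upstroke_time,
                 drift_kind = drift_kind, drift_magnitude = drift_magnitude,
                 noise_sd = noise_sd, alternans_ratio = alternans_ratio,
                 alternans_phase = alternans_phase, seed = as.integer(seed)),
            class = "trace_spec")
}

#' Construct a calcium fluorescence trace
#'
#' @param time Uniformly spaced, strictly increasing times in seconds.
#' @param intensity Fluorescence values, same length as `time`.
#' @param pacing_hz Pacing frequency used during the recording.
#' @param cell_id,group Identifiers carried through the pipeline.
#' @return An object of class `calcium_trace`.
#' @export
calcium_trace <- function(time, intensity, pacing_hz, cell_id = "cell_1",
                          group = "group_1") {
  stopifnot(length(time) == length(intensity), length(time) >= 2,
            pacing_hz > 0)
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
    stop("time must be uniformly spaced")
  }
  structure(list(time = as.numeric(time), intensity = as.numeric(intensity),
                 pacing_hz = pacing_hz, cell_id = cell_id, group = group),
            class = "calcium_trace")
}

# sampling interval of a trace
trace_dt <- function(trace) trace$time[2] - trace$time[1]

# recorded span, counting one interval per sample
trace_duration <- function(trace) length(trace$time) * trace_dt(trace)

#' Simulate one paced calcium transient trace
#'
#' Each recorded cycle starts at baseline 1.0, rises linearly over
#' `upstroke_time` to `1 + amplitude * a_k` (with `a_k` the per-beat
#' alternans factor), then decays exponentially with time constant
#' `decay_tau` until the next beat. Additive drift and Gaussian noise are
#' applied afterwards. Deterministic for a fixed spec seed.
#'
#' @param spec A [trace_spec()].
#' @param cell_id,group Identifiers for the output trace.
#' @return A [calcium_trace()].
#' @export
simulate_trace <- function(spec, cell_id = "cell_1", group = "group_1") {
  stopifnot(inherits(spec, "trace_spec"))
  phase <- spec$alternans_phase
  if (is.na(phase)) phase <- 0L
  dt <- 1 / spec$sample_rate
  n <- round(spec$n_cycles / spec$pacing_hz * spec$sample_rate)
  t <- (seq_len(n) - 1) * dt
  f <- numeric(n)
  period <- 1 / spec$pacing_hz
  for (k in seq_len(spec$n_cycles) - 1L) {
    i <- which(t >= k * period - 1e-12 & t < (k + 1) * period - 1e-12)
    t_rel <- t[i] - k * period
    a <- spec$amplitude *
      if ((k + phase) %% 2 == 1) spec$alternans_ratio else 1
    up <- t_rel <= spec$upstroke_time + 1e-12
    f[i[up]] <- 1 + a * t_rel[up] / spec$upstroke_time
    f[i[!up]] <- 1 + a * exp(-(t_rel[!up] - spec$upstroke_time) /
                               spec$decay_tau)
  }
  f <- f + switch(spec$drift_kind,
                  linear = spec$drift_magnitude * t,
                  exponential = exp(spec$drift_magnitude * t) - 1,
                  none = 0)
  if (spec$noise_sd > 0) {
    f <- f + withr::with_seed(spec$seed, rnorm(n, 0, spec$noise_sd))
  }
  calcium_trace(t, f, spec$pacing_hz, cell_id = cell_id, group = group)
}

#' Simulate a labelled population of paced cells
#'
#' Each cell receives an independent child seed from the master seed via
#' [derive_seed()], so any single cell is reproducible in isolation.
#' Optional per-cell log-normal jitter on amplitude and decay constant is
#' recorded in the manifest, as is the per-cell alternans phase (randomized
#' when the group spec's `alternans_phase` is `NA`).
#'
#' @param n_cells_per_group Cells per group (>= 1).
#' @param group_specs Named list of [trace_spec()]s, one per group.
#' @param seed Integer master seed.
#' @param jitter_cv Log-scale SD of per-cell amplitude/decay jitter
#'   (0 disables).
#' @return A list of class `cell_population` with `traces` (named list of
#'   [calcium_trace()]s) and `manifest` (per-cell parameters).
#' @export
simulate_cell_population <- function(n_cells_per_group, group_specs, seed,
                                     jitter_cv = 0) {
  stopifnot(n_cells_per_group >= 1, is.list(group_specs),
            !is.null(names(group_specs)), jitter_cv >= 0)
  traces <- list()
  rows <- list()
  counter <- 0L
  for (g in names(group_specs)) {
    spec <- group_specs[[g]]
    stopifnot(inherits(spec, "trace_spec"))
    for (j in seq_len(n_cells_per_group)) {
      counter <- counter + 1L
      cell_seed <- derive_seed(seed, counter)
      cell <- spec
      withr::with_seed(cell_seed, {
        if (jitter_cv > 0) {
          cell$amplitude <- cell$amplitude * rlnorm(1, 0, jitter_cv)
          cell$decay_tau <- cell$decay_tau * rlnorm(1, 0, jitter_cv)
        }
        if (is.na(cell$alternans_phase)) {
          cell$alternans_phase <- sample(c(0L, 1L), 1)
        }
      })
      cell$seed <- derive_seed(cell_seed, 1L)
      id <- sprintf("%s_cell_%03d", g, j)
      traces[[id]] <- simulate_trace(cell, cell_id = id, group = g)
      rows[[counter]] <- tibble::tibble(
        cell_id = id, group = g, seed = cell_seed,
        amplitude = cell$amplitude, decay_tau = cell$decay_tau,
        alternans_ratio = cell$alternans_ratio,
        alternans_phase = cell$alternans_phase)
    }
  }
  structure(list(traces = traces, manifest = do.call(rbind, rows)),
            class = "cell_population")
}

#' Write traces as a CSV (time column plus one column per cell)
#'
#' All traces must share the same time base. This layout is a package
#' convention for instrument exports.
#'
#' @param traces A `cell_population` or named list of [calcium_trace()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(traces, path) {
  if (inherits(traces, "cell_population")) traces <- traces$traces
  stopifnot(length(traces) >= 1)
  t0 <- traces[[1]]$time
  for (tr in traces) {
    if (length(tr$time) != length(t0) || max(abs(tr$time - t0)) > 1e-9) {
      stop("all traces must share the same time base")
    }
  }
  df <- data.frame(time = t0,
                   lapply(traces, function(tr) tr$intensity),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trace CSV back into calcium traces
#'
#' @param path CSV written by [write_trace_csv()].
#' @param pacing_hz Pacing frequency of the recording.
#' @param groups Optional data frame with `cell_id` and `group` columns.
#' @return Named list of [calcium_trace()]s.
#' @export
read_trace_csv <- function(path, pacing_hz, groups = NULL) {
  df <- read.csv(path, check.names = FALSE)
  stopifnot(names(df)[1] == "time", ncol(df) >= 2)
  cells <- names(df)[-1]
  grp <- setNames(rep("group_1", length(cells)), cells)
  if (!is.null(groups)) grp[groups$cell_id] <- groups$group
  out <- lapply(cells, function(id) {
    calcium_trace(df$time, df[[id]], pacing_hz, cell_id = id,
                  group = grp[[id]])
  })
  names(out) <- cells
  out
}

#' @importFrom stats setNames
NULL
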