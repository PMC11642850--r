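# shared fixture builders; everything is generated in code at test time

toy_layout <- function(barcode_length = 8, offset = 0,
                       orientation = "forward") {
  amplicon_layout("TCGGACTACC", barcode_offset = offset,
                  barcode_length = barcode_length,
                  orientation = orientation)
}

toy_library <- function(n_cm = 2, n_endo = 2, n_esc = 1, bc_len = 8,
                        seed = 11) {
  make_library(n_cm, n_endo, n_esc, barcode_length = bc_len, seed = seed)
}

# assemble a valid amplicon read for a barcode under a layout
toy_read <- function(barcode, layout, pad5 = "GG", pad3 = "TTAA") {
  paste0(pad5, layout$anchor, strrep("A", layout$barcode_offset), barcode,
         pad3)
}

# noiseless, driftless trace spec used across calcium tests
clean_spec <- function(...) {
  trace_spec(noise_sd = 0, drift_magnitude = 0, drift_kind = "none", ...)
}

# sampling interval without touching package internals
trace_dt_oracle <- function(trace) trace$time[2] - trace$time[1]

# counts -> activity table in one step, for property tests
quick_activity <- function(counts, library, pseudocount_rpm = 0) {
  rna <- counts_to_rpm(counts[, grep("^RNA", colnames(counts)), drop = FALSE])
  dna <- counts_to_rpm(counts[, grep("^DNA", colnames(counts)), drop = FALSE])
  compute_activity(rna, dna, library, pseudocount_rpm = pseudocount_rpm)
}
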