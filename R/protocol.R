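#' Build an alternating injection program
#'
#' Constructs the valve schedule for a measurement. Two protocols are
#' supported:
#'
#' * `mode = "rdc"` — repetitive direct comparison: the two sample odors are
#'   alternately injected with no carrier purge in between. The repetitions
#'   start with the *second* sample, so the first sample's injections begin at
#'   `t = interval_s, 3*interval_s, ...`; with the defaults (5 s interval,
#'   120 s run) Sample 1 starts at 5, 15, ..., 115 s.
#' * `mode = "normal"` — conventional protocol: one sample odor alternates
#'   with clean carrier gas. The same valve schedule is used with the second
#'   vial left empty, so the run likewise opens with carrier and the sample
#'   odor is first injected at `t = interval_s`. This keeps sample-injection
#'   starts at identical absolute times across both protocols, which the
#'   downstream cycle segmentation relies on.
#'
#' @param mode `"rdc"` or `"normal"`.
#' @param sample_ids Character vector of source ids: two for `"rdc"`
#'   (Sample 1 first, Sample 2 second), one for `"normal"`.
#' @param interval_s Injection interval in seconds (default 5).
#' @param total_duration_s Total measurement duration in seconds (default 120).
#' @param sampling_rate_hz Sampling frequency in Hz (default 100).
#' @param flow_rate_ml_min Gas flow rate, stored as metadata only (default 30).
#' @param carrier_id Source id used for carrier segments in normal mode.
#' @return An object of class `injection_program` with fields `segments`
#'   (data frame `source_id`, `start_s`, `duration_s`; half-open segments
#'   `[start, start + duration)` tiling `[0, total_duration)`),
#'   `sampling_rate`, `total_duration`, `mode` and `flow_rate`.
#' @examples
#' p <- build_protocol("rdc", c("S1", "S2"))
#' head(p$segments)   # starts with S2; S1 first injected at t = 5 s
#' @export
build_protocol <- function(mode, sample_ids, interval_s = 5,
                           total_duration_s = 120, sampling_rate_hz = 100,
                           flow_rate_ml_min = 30, carrier_id = "carrier") {
  mode <- match.arg(mode, c("rdc", "normal"))
  stopifnot(interval_s > 0, total_duration_s > 0, sampling_rate_hz > 0)
  n_seg <- total_duration_s / interval_s
  if (abs(n_seg - round(n_seg)) > 1e-9) {
    stop("interval_s (", interval_s, ") must divide total_duration_s (",
         total_duration_s, ")", call. = FALSE)
  }
  n_seg <- as.integer(round(n_seg))
  n_samp_per_seg <- interval_s * sampling_rate_hz
  if (abs(n_samp_per_seg - round(n_samp_per_seg)) > 1e-9) {
    stop("segment duration must be an integer multiple of the sampling period",
         call. = FALSE)
  }
  if (mode == "rdc") {
    if (length(sample_ids) != 2L || anyDuplicated(sample_ids)) {
      stop("rdc mode requires exactly two distinct sample ids", call. = FALSE)
    }
    # repetitions start with Sample 2; Sample 1 starts one interval in
    ids <- rep(c(sample_ids[2], sample_ids[1]), length.out = n_seg)
  } else {
    if (length(sample_ids) != 1L) {
      stop("normal mode requires exactly one sample id", call. = FALSE)
    }
    if (identical(sample_ids, carrier_id)) {
      stop("sample id must differ from the carrier id", call. = FALSE)
    }
    ids <- rep(c(carrier_id, sample_ids[1]), length.out = n_seg)
  }
  segments <- data.frame(
    source_id = ids,
    start_s = (seq_len(n_seg) - 1) * interval_s,
    duration_s = interval_s,
    stringsAsFactors = FALSE
  )
  structure(list(segments = segments,
                 sampling_rate = sampling_rate_hz,
                 total_duration = total_duration_s,
                 interval = interval_s,
                 mode = mode,
                 carrier_id = carrier_id,
                 flow_rate = flow_rate_ml_min),
            class = "injection_program")
}

#' @export
print.injection_program <- function(x, ...) {
  cat(sprintf("<injection_program> mode=%s  %d segments of %g s  %g s total  %g Hz\n",
              x$mode, nrow(x$segments), x$interval, x$total_duration,
              x$sampling_rate))
  invisible(x)
}

# Number of samples a trace under this program has (fence-post convention:
# t = k/fs for k = 0 .. total_duration*fs inclusive).
program_n_samples <- function(program) {
  as.integer(round(program$total_duration * program$sampling_rate)) + 1L
}

# Sample times for a program.
program_times <- function(program) {
  (seq_len(program_n_samples(program)) - 1) / program$sampling_rate
}
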