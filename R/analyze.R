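#' Extract the steady-state analysis window from a trace
#'
#' Returns the samples with `t` in the half-open interval
#' `[t_start, t_end)`, re-timed so the first retained sample is at local
#' `t = 0`. The defaults select 55-115 s, i.e. six 10 s injection cycles
#' recorded after the sensor response has settled into its cycle-periodic
#' steady state; with the standard schedule (Sample 2 first, 5 s interval)
#' an absolute time of 55 s is a Sample 1 injection start, so local 0 s marks
#' the cycle origin required by [baseline_correct()].
#'
#' @param trace A [sensor_trace].
#' @param t_start,t_end Window bounds in seconds (defaults 55 and 115). Both
#'   must lie on the sampling grid and inside the trace.
#' @param cycle_duration_s Injection cycle duration in seconds (default 10);
#'   the window length must be an integer multiple of it.
#' @return A [sensor_trace] of length `(t_end - t_start) * fs`.
#' @examples
#' tr <- sensor_trace(seq(0, 120, by = 0.01), rep(0, 12001))
#' length(extract_window(tr)$time)  # 6000
#' @export
extract_window <- function(trace, t_start = 55, t_end = 115,
                           cycle_duration_s = 10) {
  stopifnot(inherits(trace, "sensor_trace"), t_end > t_start)
  fs <- trace_rate(trace)
  k0 <- t_start * fs
  k1 <- t_end * fs
  if (abs(k0 - round(k0)) > 1e-6 || abs(k1 - round(k1)) > 1e-6) {
    stop("window boundaries must lie on the sampling grid", call. = FALSE)
  }
  ncyc <- (t_end - t_start) / cycle_duration_s
  if (abs(ncyc - round(ncyc)) > 1e-9) {
    stop("window length (", t_end - t_start,
         " s) must be an integer multiple of the cycle duration (",
         cycle_duration_s, " s)", call. = FALSE)
  }
  k0 <- as.integer(round(k0)); k1 <- as.integer(round(k1))
  if (k0 < 0 || k1 > length(trace$time) - 1L) {
    stop("window [", t_start, ", ", t_end, ") outside the trace", call. = FALSE)
  }
  idx <- (k0 + 1L):k1                      # half-open: t_end excluded
  sensor_trace((idx - idx[1]) / fs, trace$output[idx],
               channel = trace$channel, program = trace$program)
}

#' Segment a windowed trace into repetition cycles
#'
#' Splits the analysis window into `N` equal half-open cycles of
#' `cycle_duration_s` seconds. The window must start at a Sample 1 injection
#' start so that each cycle spans 5 s of Sample 1 followed by 5 s of Sample 2
#' (rDC) or carrier (normal). Concatenating the rows reproduces the window
#' sample-for-sample.
#'
#' @param windowed A [sensor_trace] as returned by [extract_window()].
#' @param cycle_duration_s Cycle duration in seconds (default 10).
#' @param expected_n If not `NULL`, assert this many cycles.
#' @return An object of class `cycle_set`: a list with `cycles` (an `N x M`
#'   matrix, one cycle per row), `time` (local cycle times, length `M`),
#'   `cycle_duration`, `sampling_rate`, `channel` and `baseline_corrected`.
#' @export
segment_cycles <- function(windowed, cycle_duration_s = 10, expected_n = NULL) {
  stopifnot(inherits(windowed, "sensor_trace"))
  fs <- trace_rate(windowed)
  m <- cycle_duration_s * fs
  if (abs(m - round(m)) > 1e-6) {
    stop("cycle duration must be an integer multiple of the sampling period",
         call. = FALSE)
  }
  m <- as.integer(round(m))
  n_samp <- length(windowed$output)
  if (n_samp %% m != 0L) {
    stop("window length (", n_samp, " samples) is not a whole number of ",
         cycle_duration_s, " s cycles", call. = FALSE)
  }
  n <- n_samp %/% m
  if (!is.null(expected_n) && n != expected_n) {
    stop("expected ", expected_n, " cycles, found ", n, call. = FALSE)
  }
  cycles <- matrix(windowed$output, nrow = n, ncol = m, byrow = TRUE)
  structure(list(cycles = cycles,
                 time = (seq_len(m) - 1) / fs,
                 cycle_duration = cycle_duration_s,
                 sampling_rate = fs,
                 channel = windowed$channel,
                 baseline_corrected = FALSE),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> %d cycles x %d samples (%g s at %g Hz)%s\n",
              nrow(x$cycles), ncol(x$cycles), x$cycle_duration,
              x$sampling_rate,
              if (x$baseline_corrected) ", baseline-corrected" else ""))
  invisible(x)
}

#' Per-cycle baseline correction
#'
#' For each repetition cycle independently, subtracts the cycle's first
#' sample (the output at the Sample 1 injection start) from all of its
#' samples, so every corrected cycle starts at exactly 0 uV. This removes
#' the slowly drifting baseline offset between repetitions while leaving the
#' within-cycle waveform untouched; the operation is idempotent.
#'
#' @param cycle_set A `cycle_set` from [segment_cycles()].
#' @return The baseline-corrected `cycle_set`.
#' @export
baseline_correct <- function(cycle_set) {
  stopifnot(inherits(cycle_set, "cycle_set"))
  cycle_set$cycles <- cycle_set$cycles - cycle_set$cycles[, 1]
  cycle_set$baseline_corrected <- TRUE
  cycle_set
}

#' Average repetition cycles
#'
#' Pointwise arithmetic mean of the (baseline-corrected) cycles. With `N`
#' repetitions carrying i.i.d. Gaussian noise this reduces the noise level by
#' a factor of `sqrt(N)`.
#'
#' @param cycle_set A `cycle_set`, normally after [baseline_correct()].
#' @return A [sensor_trace] holding the averaged cycle (local time from 0),
#'   with attribute `n_cycles`.
#' @export
average_cycles <- function(cycle_set) {
  stopifnot(inherits(cycle_set, "cycle_set"))
  avg <- colMeans(cycle_set$cycles)
  out <- sensor_trace(cycle_set$time, avg, channel = cycle_set$channel)
  attr(out, "n_cycles") <- nrow(cycle_set$cycles)
  out
}

#' Residual-RMS noise level
#'
#' Estimates the noise level of a cycle from the fit-window samples (default
#' the last second of the cycle, 9.0-10.0 s, where the sensing output is
#' close to linear): an ordinary least-squares straight line is fitted and
#' the noise level is the root mean square of its residuals. The RMS divisor
#' is the sample count `n` by default ("root mean square of the residuals"
#' taken literally); `divisor = "n-2"` gives the bias-corrected OLS residual
#' standard deviation instead.
#'
#' @param x A [sensor_trace] (e.g. an averaged cycle), a `cycle_set` (one
#'   noise level per cycle), or a numeric vector (then supply `time`).
#' @param fit_window Half-open fit interval `[t0, t1)` in local cycle
#'   seconds; default `c(9, 10)`.
#' @param divisor `"n"` (default) or `"n-2"`.
#' @param ... Passed between methods.
#' @return Noise level(s) in uV: a scalar, or one value per cycle for a
#'   `cycle_set`.
#' @examples
#' noise_level(c(0, 1, 0), time = 0:2, fit_window = c(0, 3))  # sqrt(2/9)
#' @export
noise_level <- function(x, ...) UseMethod("noise_level")

#' @rdname noise_level
#' @param time Sample times for the default (numeric-vector) method.
#' @export
noise_level.default <- function(x, time, fit_window = c(9, 10),
                                divisor = c("n", "n-2"), ...) {
  divisor <- match.arg(divisor)
  stopifnot(is.numeric(x), is.numeric(time), length(x) == length(time))
  keep <- time >= fit_window[1] & time < fit_window[2]
  y <- x[keep]; t <- time[keep]
  if (length(y) < 3L) {
    stop("fit window [", fit_window[1], ", ", fit_window[2],
         ") contains fewer than 3 samples", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, t), y)
  res <- fit$residuals
  d <- if (divisor == "n") length(res) else length(res) - 2L
  sqrt(sum(res^2) / d)
}

#' @rdname noise_level
#' @export
noise_level.sensor_trace <- function(x, fit_window = c(9, 10),
                                     divisor = c("n", "n-2"), ...) {
  noise_level.default(x$output, x$time, fit_window, divisor)
}

#' @rdname noise_level
#' @export
noise_level.cycle_set <- function(x, fit_window = c(9, 10),
                                  divisor = c("n", "n-2"), ...) {
  apply(x$cycles, 1L, noise_level.default, time = x$time,
        fit_window = fit_window, divisor = divisor)
}

#' Signal intensity of an averaged cycle
#'
#' The difference between the sensing outputs at the injection peak
#' (local `t_peak`, default 5 s, the end of the Sample 1 injection) and the
#' cycle start (local `t_start`, default 0 s). For a baseline-corrected cycle
#' this equals the 5 s sample itself. The single grid samples are used; no
#' local smoothing is applied.
#'
#' @param avg_cycle A [sensor_trace] holding one (averaged) cycle.
#' @param t_peak,t_start Peak and reference times in local seconds.
#' @return Signed signal intensity in uV.
#' @export
signal_intensity <- function(avg_cycle, t_peak = 5, t_start = 0) {
  stopifnot(inherits(avg_cycle, "sensor_trace"))
  fs <- trace_rate(avg_cycle)
  pick <- function(t) {
    k <- t * fs
    if (abs(k - round(k)) > 1e-6) {
      stop("time ", t, " s is not on the sampling grid", call. = FALSE)
    }
    k <- as.integer(round(k)) + 1L
    if (k < 1L || k > length(avg_cycle$output)) {
      stop("time ", t, " s outside the cycle", call. = FALSE)
    }
    avg_cycle$output[k]
  }
  pick(t_peak) - pick(t_start)
}

#' Theoretical noise level after averaging
#'
#' For Gaussian noise, averaging `N` repetitions reduces the noise level in
#' proportion to `1/sqrt(N)`; the theoretical reference for the averaged
#' cycle is therefore the raw noise level divided by `sqrt(N)`.
#'
#' @param noise_raw Raw (single-cycle) noise level, uV, `>= 0`.
#' @param n_repetitions Number of averaged repetitions `N >= 1`.
#' @return `noise_raw / sqrt(n_repetitions)`.
#' @export
theoretical_noise <- function(noise_raw, n_repetitions) {
  stopifnot(all(noise_raw >= 0))
  if (any(n_repetitions < 1)) stop("n_repetitions must be >= 1", call. = FALSE)
  noise_raw / sqrt(n_repetitions)
}

#' Noise of a difference of two independent traces
#'
#' Gaussian error propagation for pointwise differencing: independent noise
#' levels add in quadrature, `sqrt(sigma_a^2 + sigma_b^2)`. This is the
#' theoretical noise of the "difference of the normal measurements" route,
#' and the source of its `sqrt(2)` noise penalty relative to rDC at matched
#' per-trace noise.
#'
#' @param sigma_a,sigma_b Noise levels (uV, `>= 0`) of the two traces.
#' @return Propagated noise level in uV.
#' @export
propagate_difference_noise <- function(sigma_a, sigma_b) {
  stopifnot(all(sigma_a >= 0), all(sigma_b >= 0))
  sqrt(sigma_a^2 + sigma_b^2)
}

#' Pointwise difference of two traces
#'
#' `trace_a - trace_b` on a shared sampling grid. To mimic the rDC contrast
#' from two normal measurements of samples 1 and 2, pass the Sample 2
#' measurement as `trace_a` and the Sample 1 measurement as `trace_b`.
#'
#' @param trace_a,trace_b [sensor_trace] objects on identical grids.
#' @param channel Channel label of the result; defaults to `trace_a`'s.
#' @return A [sensor_trace] of the difference.
#' @export
difference_trace <- function(trace_a, trace_b, channel = trace_a$channel) {
  stopifnot(inherits(trace_a, "sensor_trace"), inherits(trace_b, "sensor_trace"))
  if (length(trace_a$time) != length(trace_b$time) ||
      max(abs(trace_a$time - trace_b$time)) > 1e-9) {
    stop("traces are not on the same sampling grid", call. = FALSE)
  }
  sensor_trace(trace_a$time, trace_a$output - trace_b$output,
               channel = channel, program = trace_a$program)
}

#' Consecutive-cycle convergence profile
#'
#' Measures how quickly a trace settles into its cycle-periodic steady
#' state: the trace is cut into consecutive `cycle_duration_s` cycles from
#' `t = 0` and the maximum absolute difference between each pair of
#' consecutive cycles is returned. For the noise-free first-order sorption
#' model these differences decay geometrically with ratio at most
#' `exp(-cycle_duration / tau_max)`.
#'
#' @param trace A [sensor_trace].
#' @param cycle_duration_s Cycle duration in seconds (default 10).
#' @return Numeric vector `d`, where `d[j]` is `max |cycle_{j+1} - cycle_j|`.
#' @export
cycle_convergence <- function(trace, cycle_duration_s = 10) {
  fs <- trace_rate(trace)
  m <- as.integer(round(cycle_duration_s * fs))
  n <- (length(trace$output) - 1L) %/% m   # full cycles (trailing sample dropped)
  if (n < 2L) stop("need at least two full cycles", call. = FALSE)
  cyc <- matrix(trace$output[seq_len(n * m)], nrow = n, ncol = m, byrow = TRUE)
  apply(abs(cyc[-1L, , drop = FALSE] - cyc[-n, , drop = FALSE]), 1L, max)
}

#' Steady-state onset detector
#'
#' Declares the transient over once the consecutive-cycle difference has
#' fallen below `rel_tol` times the first consecutive-cycle difference.
#' Returns the number of transient cycle transitions, i.e. 0 when the trace
#' is cycle-periodic from the start. With the default `rel_tol = 0.05`
#' (about `exp(-3)`) and geometric decay ratio `exp(-10/tau)`, detection
#' occurs within `ceiling(3 * tau / 10)` transitions.
#'
#' @inheritParams cycle_convergence
#' @param rel_tol Relative tolerance on the consecutive-cycle difference.
#' @param abs_tol Absolute floor in uV below which cycles are considered
#'   identical (guards against floating-point residue on noise-free traces).
#' @return Integer count of transient cycle transitions, or `NA` if the
#'   trace never converges within its duration.
#' @export
detect_steady_state <- function(trace, cycle_duration_s = 10, rel_tol = 0.05,
                                abs_tol = 1e-9) {
  d <- cycle_convergence(trace, cycle_duration_s)
  if (d[1] <= abs_tol) return(0L)
  hit <- which(d <= pmax(rel_tol * d[1], abs_tol))
  if (length(hit) == 0) return(NA_integer_)
  hit[1] - 1L
}

#' Full single-measurement analysis
#'
#' Runs the complete signal-processing pipeline on one trace: extract the
#' steady-state window, segment into repetition cycles, baseline-correct,
#' average, and derive the summary statistics. The "raw" noise level is the
#' mean of the per-cycle residual-RMS noise levels before averaging; the
#' averaged noise level is the residual RMS of the averaged cycle; the
#' theoretical reference divides the raw level by `sqrt(N)`. S/N is
#' `|intensity| / noise_avg`; if the averaged noise is exactly zero (an
#' ideal noise-free simulation) S/N is reported as `NA` with
#' `noise_floor = TRUE`.
#'
#' Optionally the pipeline checks, without altering any result, that the
#' window really is at steady state: if the consecutive-cycle differences
#' inside the window exceed `convergence_tol` times the window's mean
#' per-cycle amplitude, a warning is emitted.
#'
#' @param trace A [sensor_trace].
#' @param window Analysis window `c(t_start, t_end)` in seconds.
#' @param cycle_duration_s Cycle duration in seconds.
#' @param fit_window Noise fit window in local cycle seconds.
#' @param divisor RMS divisor for [noise_level()].
#' @param type Measurement type label (`"rdc"`, `"normal"`, `"difference"`,
#'   ...); defaults to the trace program's mode when available.
#' @param convergence_tol Relative threshold for the steady-state warning;
#'   `NULL` disables the check.
#' @return An object of class `measurement_summary` with fields `channel`,
#'   `type`, `n_cycles`, `intensity` (signed, uV), `noise_raw`, `noise_avg`,
#'   `noise_theory` (uV), `snr`, `noise_floor`, and the averaged cycle in
#'   `$avg_cycle`.
#' @export
analyze_measurement <- function(trace, window = c(55, 115),
                                cycle_duration_s = 10, fit_window = c(9, 10),
                                divisor = c("n", "n-2"), type = NULL,
                                convergence_tol = NULL) {
  divisor <- match.arg(divisor)
  win <- extract_window(trace, window[1], window[2], cycle_duration_s)
  cyc <- segment_cycles(win, cycle_duration_s)
  cyc <- baseline_correct(cyc)
  if (!is.null(convergence_tol)) {
    d <- apply(abs(cyc$cycles[-1L, , drop = FALSE] -
                   cyc$cycles[-nrow(cyc$cycles), , drop = FALSE]), 1L, max)
    scale <- mean(apply(abs(cyc$cycles), 1L, max))
    if (scale > 0 && any(d > convergence_tol * scale)) {
      warning("window may not be at steady state: consecutive-cycle ",
              "difference up to ", signif(max(d / scale), 3),
              " of the cycle amplitude", call. = FALSE)
    }
  }
  avg <- average_cycles(cyc)
  per_cycle <- noise_level(cyc, fit_window = fit_window, divisor = divisor)
  noise_raw <- mean(per_cycle)
  noise_avg <- noise_level(avg, fit_window = fit_window, divisor = divisor)
  intensity <- signal_intensity(avg)
  n <- nrow(cyc$cycles)
  noise_floor <- noise_avg == 0
  structure(list(channel = trace$channel,
                 type = if (is.null(type)) {
                   if (!is.null(trace$program)) trace$program$mode else "unknown"
                 } else type,
                 n_cycles = n,
                 intensity = intensity,
                 noise_raw = noise_raw,
                 noise_avg = noise_avg,
                 noise_theory = theoretical_noise(noise_raw, n),
                 snr = if (noise_floor) NA_real_ else abs(intensity) / noise_avg,
                 noise_floor = noise_floor,
                 avg_cycle = avg),
            class = "measurement_summary")
}

#' @export
print.measurement_summary <- function(x, ...) {
  cat(sprintf(
    "<measurement_summary> %s / %s: intensity %.4g uV, noise raw %.4g / avg %.4g / theory %.4g uV, S/N %.4g%s\n",
    x$channel, x$type, x$intensity, x$noise_raw, x$noise_avg, x$noise_theory,
    x$snr, if (x$noise_floor) " (noise floor 0)" else ""))
  invisible(x)
}

#' Aggregate replicate measurement summaries
#'
#' Computes the mean and sample standard deviation of intensity, noise
#' levels and S/N across replicate measurements, grouped by channel and
#' measurement type. S/N is computed per measurement *before* aggregation
#' (mean-of-ratios), which generally differs from the ratio of the mean
#' intensity to the mean noise.
#'
#' @param summaries A list of `measurement_summary` objects (at least two
#'   per channel/type group).
#' @return A data frame with one row per channel x type, columns `n` and
#'   `<field>_mean` / `<field>_sd` for intensity, noise_raw, noise_avg,
#'   noise_theory and snr.
#' @export
snr_summary <- function(summaries) {
  if (inherits(summaries, "measurement_summary")) summaries <- list(summaries)
  stopifnot(length(summaries) >= 1,
            all(vapply(summaries, inherits, TRUE, "measurement_summary")))
  df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(channel = s$channel, type = s$type, intensity = s$intensity,
               noise_raw = s$noise_raw, noise_avg = s$noise_avg,
               noise_theory = s$noise_theory, snr = s$snr,
               stringsAsFactors = FALSE)
  }))
  groups <- split(df, list(df$channel, df$type), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    if (nrow(g) < 2L) {
      stop("need at least 2 replicates per channel/type group (",
           g$channel[1], "/", g$type[1], " has ", nrow(g), ")", call. = FALSE)
    }
    fields <- c("intensity", "noise_raw", "noise_avg", "noise_theory", "snr")
    stats <- lapply(fields, function(f) {
      c(mean = mean(g[[f]]), sd = stats::sd(g[[f]]))
    })
    row <- data.frame(channel = g$channel[1], type = g$type[1], n = nrow(g),
                      stringsAsFactors = FALSE)
    for (i in seq_along(fields)) {
      row[[paste0(fields[i], "_mean")]] <- stats[[i]]["mean"]
      row[[paste0(fields[i], "_sd")]] <- stats[[i]]["sd"]
    }
    row
  }))
  rownames(out) <- NULL
  out[order(out$channel, out$type), ]
}
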