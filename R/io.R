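#' Write a sensor trace to CSV
#'
#' One file per channel: comment lines prefixed `#` carry the channel and
#' protocol metadata, followed by a `time_s,output_uV` table. Time is
#' serialised with 4 decimal places (sufficient for 100 Hz sampling) and the
#' output with 6 significant digits.
#'
#' @param trace A [sensor_trace].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sensor_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# channel: %s", trace$channel), con)
  p <- trace$program
  if (!is.null(p)) {
    writeLines(c(
      sprintf("# mode: %s", p$mode),
      sprintf("# sampling_rate_hz: %g", p$sampling_rate),
      sprintf("# total_duration_s: %g", p$total_duration),
      sprintf("# interval_s: %g", p$interval),
      sprintf("# carrier_id: %s", p$carrier_id),
      sprintf("# flow_rate_ml_min: %g", p$flow_rate),
      sprintf("# segments: %s",
              paste(p$segments$source_id, p$segments$start_s,
                    sep = "@", collapse = ";"))
    ), con)
  }
  writeLines("time_s,output_uV", con)
  writeLines(sprintf("%.4f,%.6g", trace$time, trace$output), con)
  invisible(path)
}

#' Read a sensor trace from CSV
#'
#' Reads a file written by [write_trace()] (or a real export matching the
#' schema): optional `#`-prefixed metadata lines, a `time_s,output_uV`
#' header, then the samples. The time grid is validated — non-monotone or
#' duplicated timestamps and non-finite outputs are rejected with the
#' offending line number.
#'
#' @param path File path.
#' @return A [sensor_trace]; protocol metadata, when present, is restored
#'   into `$program`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such trace file: ", path, call. = FALSE)
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- parse_trace_meta(lines[is_meta])
  body <- lines[!is_meta]
  if (length(body) < 3L || body[1] != "time_s,output_uV") {
    stop("missing 'time_s,output_uV' header in ", path, call. = FALSE)
  }
  dat <- utils::read.csv(text = body, header = TRUE)
  offset <- sum(is_meta) + 1L   # line number of the header row
  tm <- dat$time_s; out <- dat$output_uV
  if (any(!is.finite(out))) {
    stop("non-finite output at line ",
         offset + which(!is.finite(out))[1], " of ", path, call. = FALSE)
  }
  bad <- which(diff(tm) <= 0)
  if (length(bad) > 0) {
    what <- if (tm[bad[1] + 1] == tm[bad[1]]) "duplicated" else "non-monotone"
    stop(what, " timestamp at line ", offset + bad[1] + 1L, " of ", path,
         call. = FALSE)
  }
  dt <- diff(tm)
  if (max(dt) - min(dt) > 1e-6) {
    stop("irregular sampling grid near line ",
         offset + which.max(abs(dt - stats::median(dt))) + 1L, " of ", path,
         call. = FALSE)
  }
  program <- rebuild_program(meta)
  sensor_trace(tm, out, channel = meta$channel %||% "unknown",
               program = program)
}

parse_trace_meta <- function(meta_lines) {
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  meta
}

rebuild_program <- function(meta) {
  need <- c("mode", "sampling_rate_hz", "total_duration_s", "interval_s",
            "segments")
  if (!all(need %in% names(meta))) return(NULL)
  segs <- strsplit(strsplit(meta$segments, ";")[[1]], "@")
  segments <- data.frame(
    source_id = vapply(segs, `[`, "", 1L),
    start_s = as.numeric(vapply(segs, `[`, "", 2L)),
    duration_s = as.numeric(meta$interval_s),
    stringsAsFactors = FALSE
  )
  structure(list(segments = segments,
                 sampling_rate = as.numeric(meta$sampling_rate_hz),
                 total_duration = as.numeric(meta$total_duration_s),
                 interval = as.numeric(meta$interval_s),
                 mode = meta$mode,
                 carrier_id = meta$carrier_id %||% "carrier",
                 flow_rate = as.numeric(meta$flow_rate_ml_min %||% NA)),
            class = "injection_program")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 4-significant-digit fixed/float formatting used in summary files.
fmt4 <- function(x) {
  out <- formatC(x, digits = 4, format = "fg", flag = "#")
  sub("\\.$", "", trimws(out))
}

#' Render mean and standard deviation as "m ± s"
#'
#' @param mean,sd Numeric scalars or vectors.
#' @return Character, e.g. `"5.000 ± 1.414"` (4 significant digits).
#' @export
format_mean_sd <- function(mean, sd) {
  paste0(fmt4(mean), " ± ", fmt4(sd))
}

#' Write per-measurement summaries to CSV
#'
#' The machine-readable analogue of a study summary table: one row per
#' measurement with columns `channel`, `measurement_type`, `intensity_uV`,
#' `noise_raw_uV`, `noise_avg_uV`, `noise_theory_uV`, `snr`. Numbers are
#' serialised at 4 significant digits.
#'
#' @param summaries A non-empty list of `measurement_summary` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summaries, path) {
  if (inherits(summaries, "measurement_summary")) summaries <- list(summaries)
  stopifnot(length(summaries) >= 1,
            all(vapply(summaries, inherits, TRUE, "measurement_summary")))
  df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(channel = s$channel, measurement_type = s$type,
               intensity_uV = fmt4(s$intensity),
               noise_raw_uV = fmt4(s$noise_raw),
               noise_avg_uV = fmt4(s$noise_avg),
               noise_theory_uV = fmt4(s$noise_theory),
               snr = fmt4(s$snr), stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-measurement summary CSV
#'
#' @param path File written by [write_summary()].
#' @return A data frame with numeric statistic columns.
#' @export
read_summary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- c("intensity_uV", "noise_raw_uV", "noise_avg_uV", "noise_theory_uV",
           "snr")
  for (f in intersect(num, names(df))) df[[f]] <- as.numeric(df[[f]])
  df
}

#' Write an aggregated replicate report
#'
#' Renders the output of [snr_summary()] as a CSV with `mean ± sd`
#' cells for intensity, noise and S/N.
#'
#' @param table Data frame from [snr_summary()].
#' @param path Output file path, or `""` for stdout.
#' @return The rendered data frame, invisibly.
#' @export
write_report <- function(table, path = "") {
  fields <- c("intensity", "noise_raw", "noise_avg", "noise_theory", "snr")
  out <- data.frame(channel = table$channel, measurement_type = table$type,
                    n = table$n, stringsAsFactors = FALSE)
  for (f in fields) {
    out[[paste0(f, if (f == "snr") "" else "_uV")]] <-
      format_mean_sd(table[[paste0(f, "_mean")]], table[[paste0(f, "_sd")]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
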