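#' Default odor-source pair: shared base, distinct flavors
#'
#' Two "chocolate-like" sources sharing dominant base components (humidity at
#' 100, two bulk VOCs at 10 each, arbitrary concentration units) and each
#' carrying one minor distinct flavor component at 1 — the regime where
#' interfering gases are orders of magnitude more concentrated than the
#' odorants that distinguish the samples, which is exactly the situation the
#' rDC protocol targets.
#'
#' @return A list of two [odor_source] objects (`sample_A` with flavor
#'   `flavor_a`, `sample_B` with `flavor_b`).
#' @export
default_sources <- function() {
  base <- c(humidity = 100, voc_base1 = 10, voc_base2 = 10)
  list(
    odor_source("sample_A", c(base, flavor_a = 1)),
    odor_source("sample_B", c(base, flavor_b = 1))
  )
}

#' Default receptor film pair
#'
#' Two channels with PPPO-like and PS-like selectivity profiles. Sorption
#' time constants span 0.3-30 s, covering the spread of sorption and
#' viscoelastic relaxation times typical of polymer receptor layers, and the
#' responsivities differ between the channels so the two-channel structure is
#' genuinely exercised. Negative responsivities with the -1 V bridge give
#' positive-going outputs on odor injection. These are generic, plausible
#' values chosen to exercise the pipeline, not a calibration to any real
#' polymer/odorant system.
#'
#' @return A list of two [receptor_film] objects.
#' @export
default_films <- function() {
  list(
    receptor_film("PPPO_like", data.frame(
      component = c("humidity", "voc_base1", "voc_base2", "flavor_a", "flavor_b"),
      K   = c(1, 1, 1, 1, 1),
      tau = c(2, 0.3, 8, 1, 3),
      g   = -1e-6 * c(1, 2, 1.5, 8, 3)
    )),
    receptor_film("PS_like", data.frame(
      component = c("humidity", "voc_base1", "voc_base2", "flavor_a", "flavor_b"),
      K   = c(0.6, 1, 1, 1, 1),
      tau = c(3, 0.8, 30, 2, 6),
      g   = -1e-6 * c(0.8, 1, 2, 2.5, 14)
    ))
  )
}

#' Describe a synthetic rDC study
#'
#' Assembles the desk-scale analogue of the benchmark study: two sources
#' with a dominant shared base and minor distinct flavors, two receptor
#' channels, and `replicates` repeats of the measurement set
#' {normal on sample A, normal on sample B, rDC(A, B)} under the standard
#' protocol (5 s alternation, 120 s runs, 100 Hz, bridge at -1 V). The
#' default Gaussian noise of 1 uV puts the raw single-cycle rDC
#' signal-to-noise around 5, so averaging has a visible but non-trivial
#' effect; a small linear drift emulates the slow baseline shift of real
#' hardware.
#'
#' @param sources List of two [odor_source] objects (Sample 1 first). Their
#'   shared components must all be more concentrated than any distinct one.
#' @param films List of [receptor_film] channels.
#' @param replicates Number of measurement-set repeats (default 6).
#' @param interval_s,total_duration_s,sampling_rate_hz Protocol parameters.
#' @param bridge A [bridge_config].
#' @param gaussian_sigma Gaussian noise level, uV.
#' @param drift_slope Baseline drift, uV/s.
#' @param undulation Optional undulation settings (see [noise_model()]).
#' @param window,fit_window,cycle_duration_s Analysis parameters.
#' @param seed Base integer seed; all per-trace seeds are derived from it.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(sources = default_sources(),
                              films = default_films(),
                              replicates = 6,
                              interval_s = 5, total_duration_s = 120,
                              sampling_rate_hz = 100,
                              bridge = bridge_config(vb = -1.0),
                              gaussian_sigma = 1.0, drift_slope = 0.05,
                              undulation = NULL,
                              window = c(55, 115), fit_window = c(9, 10),
                              cycle_duration_s = 10,
                              seed = 1L) {
  sources <- as_source_list(sources)
  stopifnot(length(sources) == 2L, length(films) >= 1L, replicates >= 1L)
  shared <- intersect(names(sources[[1]]$concentrations),
                      names(sources[[2]]$concentrations))
  distinct <- setdiff(unique(c(names(sources[[1]]$concentrations),
                               names(sources[[2]]$concentrations))), shared)
  if (length(shared) > 0 && length(distinct) > 0) {
    cmax <- max(c(sources[[1]]$concentrations[intersect(distinct, names(sources[[1]]$concentrations))],
                  sources[[2]]$concentrations[intersect(distinct, names(sources[[2]]$concentrations))]))
    cmin <- min(sources[[1]]$concentrations[shared], sources[[2]]$concentrations[shared])
    if (cmin <= cmax) {
      stop("shared (interfering) components must be more concentrated than ",
           "every distinct (flavor) component", call. = FALSE)
    }
  }
  structure(list(sources = sources, films = films,
                 replicates = as.integer(replicates),
                 interval_s = interval_s,
                 total_duration_s = total_duration_s,
                 sampling_rate_hz = sampling_rate_hz,
                 bridge = bridge,
                 gaussian_sigma = gaussian_sigma,
                 drift_slope = drift_slope,
                 undulation = undulation,
                 window = window, fit_window = fit_window,
                 cycle_duration_s = cycle_duration_s,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

# Protocols making up one measurement set.
study_protocols <- c("normal_s1", "normal_s2", "rdc")

# Deterministic per-trace seed schedule: distinct for every
# (replicate, protocol, channel) triple.
trace_seed <- function(design, replicate, protocol, channel_idx) {
  p <- match(protocol, study_protocols)
  offset <- ((replicate - 1L) * length(study_protocols) + (p - 1L)) *
    length(design$films) + (channel_idx - 1L)
  design$seed + offset * 1009L
}

#' Generate all traces of a synthetic study
#'
#' Simulates `replicates x {normal_s1, normal_s2, rdc} x channels` sensor
#' traces under the design, each with its own derived seed, and returns them
#' with a manifest. Regeneration from the same design is bit-identical. If
#' `out_dir` is given, every trace is additionally written as a CSV (see
#' [write_trace()]) along with `manifest.csv`.
#'
#' @param design An [experiment_design].
#' @param out_dir Optional output directory for trace and manifest files.
#' @return A list with `traces` (named list of [sensor_trace]) and
#'   `manifest` (data frame: `id`, `protocol`, `replicate`, `channel`,
#'   `seed`, and `file` when written).
#' @export
generate_experiment <- function(design, out_dir = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  s1 <- design$sources[[1]]$name
  s2 <- design$sources[[2]]$name
  programs <- list(
    normal_s1 = build_protocol("normal", s1, design$interval_s,
                               design$total_duration_s, design$sampling_rate_hz),
    normal_s2 = build_protocol("normal", s2, design$interval_s,
                               design$total_duration_s, design$sampling_rate_hz),
    rdc = build_protocol("rdc", c(s1, s2), design$interval_s,
                         design$total_duration_s, design$sampling_rate_hz)
  )
  rows <- expand.grid(channel_idx = seq_along(design$films),
                      protocol = study_protocols,
                      replicate = seq_len(design$replicates),
                      stringsAsFactors = FALSE)
  seeds <- mapply(trace_seed, rows$replicate, rows$protocol, rows$channel_idx,
                  MoreArgs = list(design = design))
  if (anyDuplicated(seeds)) stop("seed collision in the schedule", call. = FALSE)
  traces <- vector("list", nrow(rows))
  ids <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    film <- design$films[[rows$channel_idx[i]]]
    nm <- noise_model(design$gaussian_sigma, design$drift_slope,
                      design$undulation, seed = seeds[i])
    traces[[i]] <- simulate_measurement(design$sources, film,
                                        programs[[rows$protocol[i]]],
                                        design$bridge, nm)
    ids[i] <- sprintf("%s_rep%d_%s", rows$protocol[i], rows$replicate[i],
                      film$name)
  }
  names(traces) <- ids
  manifest <- data.frame(id = ids, protocol = rows$protocol,
                         replicate = rows$replicate,
                         channel = vapply(design$films[rows$channel_idx],
                                          function(f) f$name, ""),
                         seed = as.integer(seeds),
                         stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest$file <- paste0(manifest$id, ".csv")
    for (i in seq_len(nrow(manifest))) {
      write_trace(traces[[i]], file.path(out_dir, manifest$file[i]))
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(traces = traces, manifest = manifest)
}

#' Run the full synthetic study end to end
#'
#' Generates the study traces, analyses every rDC measurement and every
#' difference of the paired normal measurements (sample B minus sample A,
#' i.e. Sample 2 minus Sample 1), and aggregates replicate statistics. The
#' output mirrors the structure of a benchmark summary table: one row per
#' channel and method with mean and standard deviation of signal intensity,
#' noise levels and S/N.
#'
#' @param design An [experiment_design].
#' @param include_normals Also analyse and report the individual normal
#'   measurements (default `FALSE`).
#' @return A list with `table` (the aggregated data frame from
#'   [snr_summary()]), `summaries` (all per-measurement summaries) and
#'   `manifest`.
#' @export
run_study <- function(design, include_normals = FALSE) {
  gen <- generate_experiment(design)
  analyze1 <- function(trace, type) {
    analyze_measurement(trace, window = design$window,
                        cycle_duration_s = design$cycle_duration_s,
                        fit_window = design$fit_window, type = type)
  }
  summaries <- list()
  for (r in seq_len(design$replicates)) {
    for (f in design$films) {
      tr_rdc <- gen$traces[[sprintf("rdc_rep%d_%s", r, f$name)]]
      tr_n1 <- gen$traces[[sprintf("normal_s1_rep%d_%s", r, f$name)]]
      tr_n2 <- gen$traces[[sprintf("normal_s2_rep%d_%s", r, f$name)]]
      summaries <- c(summaries, list(analyze1(tr_rdc, "rdc")))
      summaries <- c(summaries,
                     list(analyze1(difference_trace(tr_n2, tr_n1), "difference")))
      if (include_normals) {
        summaries <- c(summaries, list(analyze1(tr_n1, "normal_s1"),
                                       analyze1(tr_n2, "normal_s2")))
      }
    }
  }
  tab <- if (design$replicates >= 2L) snr_summary(summaries) else NULL
  list(table = tab, summaries = summaries, manifest = gen$manifest)
}
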