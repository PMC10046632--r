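#' Read and validate a run configuration
#'
#' Run configurations are YAML files with a flat block hierarchy:
#' `sources`, `films`, `bridge`, `protocol`, `noise`, `analysis`,
#' `replicates`. Unknown top-level keys (and unknown keys inside each block)
#' are rejected so that typos cannot silently fall back to defaults. A
#' committed example with all recognised keys ships as
#' `system.file("extdata", "example_config.yaml", package = "rdcsense")`.
#'
#' @param path Path to the YAML configuration file.
#' @return A list with elements `sources` (list of [odor_source]), `films`
#'   (list of [receptor_film]), `bridge` ([bridge_config]), `protocol`
#'   (list of protocol parameters), `noise` (list), `analysis` (list) and
#'   `replicates`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c("sources", "films", "bridge", "protocol", "noise", "analysis",
             "replicates")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  check_keys <- function(block, allowed, where) {
    bad <- setdiff(names(block), allowed)
    if (length(bad) > 0) {
      stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }

  sources <- lapply(names(raw$sources %||% list()), function(nm) {
    odor_source(nm, unlist(raw$sources[[nm]]))
  })

  films <- lapply(names(raw$films %||% list()), function(nm) {
    comps <- raw$films[[nm]]
    params <- do.call(rbind, lapply(names(comps), function(cid) {
      check_keys(comps[[cid]], c("K", "tau", "g"),
                 paste0("films/", nm, "/", cid))
      data.frame(component = cid,
                 K = as.numeric(comps[[cid]]$K %||% 0),
                 tau = as.numeric(comps[[cid]]$tau %||% 1),
                 g = as.numeric(comps[[cid]]$g %||% 0))
    }))
    receptor_film(nm, params)
  })

  br <- raw$bridge %||% list()
  check_keys(br, c("vb", "weights"), "bridge")
  bridge <- bridge_config(vb = br$vb %||% -1.0,
                          weights = unlist(br$weights %||% c(1, -1, 1, -1)))

  pr <- raw$protocol %||% list()
  check_keys(pr, c("mode", "samples", "interval_s", "total_duration_s",
                   "sampling_rate_hz", "flow_rate_ml_min", "carrier_id"),
             "protocol")
  protocol <- list(mode = pr$mode %||% "rdc",
                   samples = unlist(pr$samples %||% character()),
                   interval_s = pr$interval_s %||% 5,
                   total_duration_s = pr$total_duration_s %||% 120,
                   sampling_rate_hz = pr$sampling_rate_hz %||% 100,
                   flow_rate_ml_min = pr$flow_rate_ml_min %||% 30,
                   carrier_id = pr$carrier_id %||% "carrier")

  no <- raw$noise %||% list()
  check_keys(no, c("gaussian_sigma_uV", "drift_slope_uV_per_s", "undulation"),
             "noise")
  und <- NULL
  if (!is.null(no$undulation)) {
    check_keys(no$undulation,
               c("amplitude_uV", "frequency_hz", "phase_rad"),
               "noise/undulation")
    und <- list(amplitude = no$undulation$amplitude_uV %||% 0,
                frequency = no$undulation$frequency_hz %||% 1,
                phase = no$undulation$phase_rad %||% 0)
  }
  # absent noise keys fall back to the default study conditions
  noise <- list(gaussian_sigma = no$gaussian_sigma_uV %||% 1.0,
                drift_slope = no$drift_slope_uV_per_s %||% 0.05,
                undulation = und)

  an <- raw$analysis %||% list()
  check_keys(an, c("window_s", "cycle_duration_s", "fit_window_s"), "analysis")
  analysis <- list(window = unlist(an$window_s %||% c(55, 115)),
                   cycle_duration_s = an$cycle_duration_s %||% 10,
                   fit_window = unlist(an$fit_window_s %||% c(9, 10)))

  list(sources = sources, films = films, bridge = bridge,
       protocol = protocol, noise = noise, analysis = analysis,
       replicates = raw$replicates %||% 6)
}

#' Build an experiment design from a run configuration
#'
#' @param config A list as returned by [read_run_config()]; blocks left out
#'   of the file fall back to the package defaults of [experiment_design()].
#' @param seed Base seed for the derived per-trace seed schedule.
#' @return An [experiment_design].
#' @export
design_from_config <- function(config, seed = 1L) {
  experiment_design(
    sources = if (length(config$sources) > 0) config$sources else default_sources(),
    films = if (length(config$films) > 0) config$films else default_films(),
    replicates = config$replicates,
    interval_s = config$protocol$interval_s,
    total_duration_s = config$protocol$total_duration_s,
    sampling_rate_hz = config$protocol$sampling_rate_hz,
    bridge = config$bridge,
    gaussian_sigma = config$noise$gaussian_sigma,
    drift_slope = config$noise$drift_slope,
    undulation = config$noise$undulation,
    window = config$analysis$window,
    fit_window = config$analysis$fit_window,
    cycle_duration_s = config$analysis$cycle_duration_s,
    seed = seed
  )
}

#' Write a machine-readable provenance record
#'
#' Every CLI output directory gets a `provenance.json` recording the config
#' file hash, the seed and the package version, so any run can be
#' reproduced exactly.
#'
#' @param out_dir Output directory.
#' @param config_path Path of the config file used (or `NULL`).
#' @param seed The seed used.
#' @return Path of the written file, invisibly.
#' @export
write_provenance <- function(out_dir, config_path, seed) {
  rec <- list(
    config = if (is.null(config_path)) NA_character_ else basename(config_path),
    config_md5 = if (is.null(config_path)) NA_character_
                 else unname(tools::md5sum(config_path)),
    seed = as.integer(seed),
    package = "rdcsense",
    version = as.character(utils::packageVersion("rdcsense"))
  )
  path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
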