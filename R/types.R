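#' Define an odor source
#'
#' An odor source is a named mixture of gas components, each at a fixed
#' headspace concentration. The rDC protocol is designed for pairs of sources
#' that share dominant "base" components (humidity, bulk VOCs) and differ only
#' in minor flavor components; [experiment_design()] builds such a pair.
#'
#' @param name Source label (e.g. `"sample_A"`).
#' @param concentrations Named numeric vector mapping component ids to
#'   concentrations (arbitrary concentration units, all finite and
#'   non-negative). May be empty, which describes clean carrier gas.
#' @return An object of class `odor_source`.
#' @examples
#' odor_source("sample_A", c(humidity = 100, ethanol = 10, furaneol = 1))
#' @export
odor_source <- function(name, concentrations = numeric()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  conc <- unlist(concentrations)
  if (length(conc) > 0) {
    if (is.null(names(conc)) || any(!nzchar(names(conc)))) {
      stop("all concentrations must be named by component id", call. = FALSE)
    }
    if (anyDuplicated(names(conc))) {
      stop("duplicated component ids in source '", name, "'", call. = FALSE)
    }
    if (!all(is.finite(conc)) || any(conc < 0)) {
      stop("concentrations must be finite and non-negative", call. = FALSE)
    }
  }
  structure(list(name = name, concentrations = conc), class = "odor_source")
}

#' The clean carrier gas pseudo-source
#'
#' Deodorized, dehumidified air: a source with no components. Normal
#' measurements alternate a sample odor with this carrier.
#'
#' @param name Label used in injection programs; defaults to `"carrier"`.
#' @return An `odor_source` with an empty concentration map.
#' @export
carrier_gas <- function(name = "carrier") odor_source(name, numeric())

#' Define a receptor film (sensor channel)
#'
#' One polymer-coated MSS channel. Gas sorption into the film is modelled per
#' component by first-order kinetics with partition coefficient `K`
#' (equilibrium sorbed quantity per unit concentration), time constant `tau`
#' (seconds), and responsivity `g` (fractional bridge resistance change per
#' unit sorbed quantity; signed). Components that a source delivers but the
#' film does not parameterise default to `K = 0` (no sorption).
#'
#' @param name Film label (e.g. `"PPPO"`, `"PS"`).
#' @param params A data frame with columns `component`, `K`, `tau`, `g`.
#' @param tau_range Admissible range for sorption time constants, in seconds.
#' @return An object of class `receptor_film`.
#' @examples
#' receptor_film("PPPO", data.frame(
#'   component = c("humidity", "ethanol"),
#'   K = c(1, 0.5), tau = c(2, 0.3), g = c(-1e-6, -2e-6)
#' ))
#' @export
receptor_film <- function(name, params, tau_range = c(0.05, 200)) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.data.frame(params),
            all(c("component", "K", "tau", "g") %in% names(params)))
  params$component <- as.character(params$component)
  if (anyDuplicated(params$component)) {
    stop("duplicated component ids in film '", name, "'", call. = FALSE)
  }
  if (any(!is.finite(params$K)) || any(params$K < 0)) {
    stop("partition coefficients K must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(params$tau)) || any(params$tau <= 0)) {
    stop("time constants tau must be finite and > 0", call. = FALSE)
  }
  if (any(params$tau < tau_range[1] | params$tau > tau_range[2])) {
    stop("time constants tau outside admissible range [",
         tau_range[1], ", ", tau_range[2], "] s", call. = FALSE)
  }
  if (any(!is.finite(params$g))) {
    stop("responsivities g must be finite", call. = FALSE)
  }
  structure(list(name = name,
                 params = params[, c("component", "K", "tau", "g")],
                 tau_range = tau_range),
            class = "receptor_film")
}

#' Wheatstone-bridge readout configuration
#'
#' The four piezoresistors of an MSS form a full Wheatstone bridge read as
#' `Vout = (VB/4) * (dR1/R1 - dR2/R2 + dR3/R3 - dR4/R4)`. The film strain
#' signal `s(t)` distributes over the arms with signed weights; the default
#' pattern `(+1, -1, +1, -1)` yields `Vout = VB * s(t)`.
#'
#' @param vb Bridge voltage in volts (default -1.0 V).
#' @param weights Signed weights mapping `s(t)` to the four fractional
#'   resistance changes.
#' @return An object of class `bridge_config`.
#' @export
bridge_config <- function(vb = -1.0, weights = c(1, -1, 1, -1)) {
  stopifnot(is.numeric(vb), length(vb) == 1L, is.finite(vb))
  stopifnot(is.numeric(weights), length(weights) == 4L, all(is.finite(weights)))
  structure(list(vb = vb, weights = weights), class = "bridge_config")
}

#' Measurement noise and baseline-drift model
#'
#' Additive, stationary disturbances: i.i.d. Gaussian noise, a linear baseline
#' drift (thermal), and optionally a single sinusoidal undulation mimicking
#' the non-Gaussian periodic disturbances (pump/valve electronics) seen on
#' real hardware. The seed is a mandatory explicit input; no global random
#' state is consulted or modified.
#'
#' @param gaussian_sigma Standard deviation of the white noise, in uV.
#' @param drift_slope Baseline drift, in uV/s.
#' @param undulation `NULL`, or a list with elements `amplitude` (uV, >= 0),
#'   `frequency` (Hz, > 0) and `phase` (rad, optional, default 0).
#' @param seed Integer seed for the Gaussian noise.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(gaussian_sigma = 0, drift_slope = 0,
                        undulation = NULL, seed = 1L) {
  stopifnot(is.numeric(gaussian_sigma), gaussian_sigma >= 0,
            is.finite(gaussian_sigma))
  stopifnot(is.numeric(drift_slope), is.finite(drift_slope))
  if (!is.null(undulation)) {
    stopifnot(is.list(undulation),
              all(c("amplitude", "frequency") %in% names(undulation)))
    stopifnot(undulation$amplitude >= 0, undulation$frequency > 0)
    if (is.null(undulation$phase)) undulation$phase <- 0
  }
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  structure(list(gaussian_sigma = gaussian_sigma, drift_slope = drift_slope,
                 undulation = undulation, seed = seed),
            class = "noise_model")
}

#' Construct a sensor trace
#'
#' A uniformly sampled sensing-output time series for one channel. Samples
#' lie at `t = k / sampling_rate` for `k = 0 .. total_duration*sampling_rate`
#' (both endpoints included).
#'
#' @param time Sample times in seconds, strictly increasing, constant step.
#' @param output Sensing output in uV, finite.
#' @param channel Film/channel name.
#' @param program The [injection_program] the trace was recorded under, or
#'   `NULL` for bare traces.
#' @return An object of class `sensor_trace`.
#' @export
sensor_trace <- function(time, output, channel = "unknown", program = NULL) {
  stopifnot(is.numeric(time), is.numeric(output),
            length(time) == length(output), length(time) >= 2L)
  if (!all(is.finite(output))) stop("output contains non-finite values", call. = FALSE)
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-9 * max(dt)) {
    stop("time grid is not uniform", call. = FALSE)
  }
  structure(list(time = as.numeric(time), output = as.numeric(output),
                 channel = channel, program = program),
            class = "sensor_trace")
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat(sprintf("<sensor_trace> channel=%s  n=%d  t=[%g, %g] s  fs=%g Hz\n",
              x$channel, length(x$time), x$time[1], x$time[length(x$time)],
              1 / (x$time[2] - x$time[1])))
  invisible(x)
}

#' @export
print.odor_source <- function(x, ...) {
  cat(sprintf("<odor_source> %s: %s\n", x$name,
              if (length(x$concentrations) == 0) "(carrier, no components)"
              else paste(names(x$concentrations), x$concentrations,
                         sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
print.receptor_film <- function(x, ...) {
  cat(sprintf("<receptor_film> %s (%d components)\n", x$name, nrow(x$params)))
  print(x$params, row.names = FALSE)
  invisible(x)
}

# Sampling rate of a trace (Hz), derived from the grid.
trace_rate <- function(trace) 1 / (trace$time[2] - trace$time[1])
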