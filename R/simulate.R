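#' Per-component sorbed-quantity time series
#'
#' Forward model of gas sorption into a receptor film. Each component `i`
#' follows first-order relaxation towards its partition equilibrium,
#' `dq_i/dt = (K_i * c_i(t) - q_i) / tau_i`, with `q_i(0) = 0`, where
#' `c_i(t)` is the concentration delivered by the injection segment active at
#' time `t`. Because `c_i` is piecewise constant, the solution is advanced
#' segment-by-segment with the exact exponential update
#' `q(t) = K c + (q0 - K c) exp(-(t - t0)/tau)`, evaluated on the sampling
#' grid — there is no numerical-integrator tolerance involved.
#'
#' Components delivered by a source but not parameterised in the film default
#' to `K = 0` (no sorption, no response).
#'
#' @param program An [injection_program].
#' @param sources A list of [odor_source] objects covering every source id in
#'   the program (the program's carrier id may be omitted; it is treated as a
#'   zero-concentration source).
#' @param film A [receptor_film].
#' @return A numeric matrix, `program_n_samples x n_components`, with
#'   component ids as column names; `attr(, "time")` holds the sample times.
#' @examples
#' p <- build_protocol("normal", "A", 5, 10, 100)
#' src <- list(odor_source("A", c(x = 1)))
#' film <- receptor_film("F", data.frame(component = "x", K = 1, tau = 1, g = 1e-6))
#' q <- sorbed_response(p, src, film)
#' @export
sorbed_response <- function(program, sources, film) {
  stopifnot(inherits(program, "injection_program"),
            inherits(film, "receptor_film"))
  sources <- as_source_list(sources)
  needed <- setdiff(unique(program$segments$source_id), program$carrier_id)
  missing_src <- setdiff(needed, names(sources))
  if (length(missing_src) > 0) {
    stop("program references unknown source(s): ",
         paste(missing_src, collapse = ", "), call. = FALSE)
  }
  comps <- unique(c(unlist(lapply(sources, function(s) names(s$concentrations))),
                    film$params$component))
  if (length(comps) == 0) {
    q <- matrix(0, program_n_samples(program), 0)
    attr(q, "time") <- program_times(program)
    return(q)
  }
  # film parameters aligned to the full component set; unknowns get K = 0
  idx <- match(comps, film$params$component)
  K   <- ifelse(is.na(idx), 0, film$params$K[idx])
  tau <- ifelse(is.na(idx), 1, film$params$tau[idx])

  fs <- program$sampling_rate
  n  <- program_n_samples(program)
  q  <- matrix(0, n, length(comps), dimnames = list(NULL, comps))
  state <- numeric(length(comps))  # q at the running segment start

  conc_of <- function(id) {
    if (identical(id, program$carrier_id) && is.null(sources[[id]])) {
      return(numeric(length(comps)))
    }
    cvec <- sources[[id]]$concentrations
    out <- numeric(length(comps))
    m <- match(names(cvec), comps)
    out[m] <- cvec
    out
  }

  for (j in seq_len(nrow(program$segments))) {
    seg <- program$segments[j, ]
    c_seg <- conc_of(seg$source_id)
    k0 <- as.integer(round(seg$start_s * fs))            # first sample index (0-based)
    n_loc <- as.integer(round(seg$duration_s * fs))      # samples in [start, end)
    last_seg <- j == nrow(program$segments)
    # the final grid point t = total_duration extends the last segment
    t_loc <- (0:(n_loc - 1L + as.integer(last_seg))) / fs
    eq <- K * c_seg
    # exact exponential relaxation within the segment, all components at once
    decay <- exp(outer(t_loc, tau, function(t, tt) -t / tt))
    q_seg <- sweep(decay, 2, state - eq, `*`)
    q_seg <- sweep(q_seg, 2, eq, `+`)
    rows <- k0 + seq_len(nrow(q_seg))
    q[rows, ] <- q_seg
    # carry state to the segment end
    state <- eq + (state - eq) * exp(-seg$duration_s / tau)
  }
  attr(q, "time") <- program_times(program)
  q
}

#' Wheatstone-bridge transduction
#'
#' Converts a film strain signal into the bridge output voltage. The MSS
#' readout is `Vout = (VB/4) (dR1/R1 - dR2/R2 + dR3/R3 - dR4/R4)`; with arm
#' weights `w` the strain `s(t)` produces
#' `Vout(t) = (VB/4) (w1 - w2 + w3 - w4) s(t)`, reported in microvolts. The
#' default pattern `(+1, -1, +1, -1)` gives `Vout = VB * s(t)`.
#'
#' @param strain Numeric vector: fractional resistance-change signal `s(t)`
#'   (dimensionless).
#' @param bridge A [bridge_config].
#' @return Output in uV, same length as `strain`.
#' @examples
#' transduce_bridge(1e-5, bridge_config(vb = -1)) # -10 uV
#' @export
transduce_bridge <- function(strain, bridge = bridge_config()) {
  stopifnot(inherits(bridge, "bridge_config"))
  if (!all(is.finite(strain))) stop("strain must be finite", call. = FALSE)
  w <- bridge$weights
  gain <- (bridge$vb / 4) * (w[1] - w[2] + w[3] - w[4])
  gain * strain * 1e6
}

#' Add noise, drift and undulation to a trace
#'
#' Applies the additive disturbance model: a linear baseline drift
#' `drift_slope * t`, i.i.d. Gaussian noise, and an optional sinusoidal
#' undulation. The random stream is seeded from the model's `seed` and the
#' caller's random state is left untouched, so identical inputs always yield
#' identical traces.
#'
#' @param trace A [sensor_trace].
#' @param noise A [noise_model].
#' @return A new [sensor_trace] with the disturbances added.
#' @export
add_noise_and_drift <- function(trace, noise) {
  stopifnot(inherits(trace, "sensor_trace"), inherits(noise, "noise_model"))
  t <- trace$time
  y <- trace$output + noise$drift_slope * t
  if (!is.null(noise$undulation)) {
    u <- noise$undulation
    y <- y + u$amplitude * sin(2 * pi * u$frequency * t + u$phase)
  }
  if (noise$gaussian_sigma > 0) {
    y <- y + local_rnorm(noise$seed, length(t), sd = noise$gaussian_sigma)
  }
  sensor_trace(t, y, channel = trace$channel, program = trace$program)
}

#' Simulate one complete measurement
#'
#' Composes the forward model end to end: per-component sorption kinetics
#' ([sorbed_response]), summation into a film strain
#' `s(t) = sum_i g_i q_i(t)`, bridge transduction ([transduce_bridge]) and
#' the noise model ([add_noise_and_drift]). The result is deterministic given
#' the noise model's seed.
#'
#' @inheritParams sorbed_response
#' @param bridge A [bridge_config].
#' @param noise A [noise_model], or `NULL` for a noise-free trace.
#' @return A [sensor_trace] for the film channel.
#' @export
simulate_measurement <- function(sources, film, program,
                                 bridge = bridge_config(), noise = NULL) {
  q <- sorbed_response(program, sources, film)
  comps <- colnames(q)
  idx <- match(comps, film$params$component)
  g <- ifelse(is.na(idx), 0, film$params$g[idx])
  strain <- if (length(comps) == 0) numeric(nrow(q)) else as.numeric(q %*% g)
  out <- transduce_bridge(strain, bridge)
  trace <- sensor_trace(attr(q, "time"), out, channel = film$name,
                        program = program)
  if (!is.null(noise)) trace <- add_noise_and_drift(trace, noise)
  trace
}

# Normalise a list of odor_source objects into a named list.
as_source_list <- function(sources) {
  if (inherits(sources, "odor_source")) sources <- list(sources)
  stopifnot(is.list(sources), all(vapply(sources, inherits, TRUE, "odor_source")))
  names(sources) <- vapply(sources, function(s) s$name, "")
  sources
}

# Draw from N(0, sd) under an explicit seed without touching the caller's
# random state.
local_rnorm <- function(seed, n, sd = 1) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}
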