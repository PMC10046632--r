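# Shared fixture builders. Everything is generated in code; no data files.

# Single-component source/film pair with controllable kinetics.
one_comp_source <- function(name = "A", conc = 1, comp = "x") {
  cc <- conc
  names(cc) <- comp
  odor_source(name, cc)
}

one_comp_film <- function(K = 1, tau = 1, g = 1e-6, comp = "x",
                          name = "film") {
  receptor_film(name, data.frame(component = comp, K = K, tau = tau, g = g))
}

# A bare trace holding an arbitrary signal on the standard 100 Hz grid.
signal_trace <- function(f, duration = 120, fs = 100, channel = "ch") {
  t <- seq(0, duration, by = 1 / fs)
  sensor_trace(t, f(t), channel = channel)
}

# Clean cycle-periodic waveform (period 10 s) resembling a sorption response.
periodic_signal <- function(t, amp = 10) {
  phase <- t %% 10
  amp * ifelse(phase < 5, 1 - exp(-phase / 0.8),
               (1 - exp(-5 / 0.8)) * exp(-(phase - 5) / 0.8))
}

# Fast-kinetics two-source design: steady state is reached well before the
# 55 s window, so superposition identities hold to tight tolerance.
fast_design <- function(sigma = 0, drift = 0, seed = 1, replicates = 2) {
  base <- c(humidity = 100, voc = 10)
  sources <- list(odor_source("A", c(base, fa = 1)),
                  odor_source("B", c(base, fb = 1)))
  films <- list(receptor_film("F1", data.frame(
    component = c("humidity", "voc", "fa", "fb"),
    K = c(1, 1, 1, 1), tau = c(2, 0.5, 1, 1.5),
    g = -1e-6 * c(1, 2, 8, 3)
  )))
  experiment_design(sources = sources, films = films,
                    replicates = replicates, gaussian_sigma = sigma,
                    drift_slope = drift, seed = seed)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(abs(actual - expected), rel_tol * abs(expected))
}
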