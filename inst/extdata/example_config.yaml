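# Example run configuration for rdcsense.
# All recognised keys are shown; blocks may be omitted to use package
# defaults. Concentrations are in arbitrary concentration units, K is
# dimensionless, tau in seconds, g is the fractional bridge resistance
# change per unit sorbed quantity.
sources:
  sample_A:                 # Sample 1 (vanilla-flavored analogue)
    humidity: 100           # dominant shared interferent
    voc_base1: 10
    voc_base2: 10
    flavor_a: 1             # minor distinct flavor component
  sample_B:                 # Sample 2 (strawberry-flavored analogue)
    humidity: 100
    voc_base1: 10
    voc_base2: 10
    flavor_b: 1
films:
  PPPO_like:
    humidity:  {K: 1.0, tau: 2.0,  g: -1.0e-6}
    voc_base1: {K: 1.0, tau: 0.3,  g: -2.0e-6}
    voc_base2: {K: 1.0, tau: 8.0,  g: -1.5e-6}
    flavor_a:  {K: 1.0, tau: 1.0,  g: -8.0e-6}
    flavor_b:  {K: 1.0, tau: 3.0,  g: -3.0e-6}
  PS_like:
    humidity:  {K: 0.6, tau: 3.0,  g: -0.8e-6}
    voc_base1: {K: 1.0, tau: 0.8,  g: -1.0e-6}
    voc_base2: {K: 1.0, tau: 30.0, g: -2.0e-6}
    flavor_a:  {K: 1.0, tau: 2.0,  g: -2.5e-6}
    flavor_b:  {K: 1.0, tau: 6.0,  g: -14.0e-6}
bridge:
  vb: -1.0                  # bridge voltage, volts
  weights: [1, -1, 1, -1]   # arm pattern: Vout = VB * s(t)
protocol:
  mode: rdc                 # rdc | normal
  samples: [sample_A, sample_B]
  interval_s: 5
  total_duration_s: 120
  sampling_rate_hz: 100
  flow_rate_ml_min: 30      # metadata only
noise:
  gaussian_sigma_uV: 1.0
  drift_slope_uV_per_s: 0.05
  # undulation: {amplitude_uV: 0.5, frequency_hz: 0.3, phase_rad: 0}
analysis:
  window_s: [55, 115]       # steady-state analysis window
  cycle_duration_s: 10
  fit_window_s: [9, 10]     # noise fit: last 1 s of each cycle
replicates: 6
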