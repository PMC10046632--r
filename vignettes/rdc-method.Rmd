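---
title: "Repetitive direct comparison: model and signal-processing methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repetitive direct comparison: model and signal-processing methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdcsense)
```

## The measurement problem

Two odor samples that differ only in minor flavor volatiles produce nearly
identical responses on a broadband gas sensor, because the response is
dominated by components the samples share — above all humidity and bulk
VOCs, often orders of magnitude more concentrated than the distinguishing
odorants. The repetitive direct comparison (rDC) protocol attacks this at
the measurement level: the two samples' headspaces are injected
alternately, with no carrier purge in between. Components common to both
samples then hold the receptor film at a constant sorbed level and drop out
of the alternating signal; only the differing components modulate the
output. Because the film is never purged, the response converges to a
cycle-periodic steady state after a few alternations, and the repeated
cycles can be averaged — bringing classic signal averaging, with its
$1/\sqrt{N}$ noise reduction, to a sensor class where it is normally
defeated by residual-gas memory.

`rdcsense` implements both halves of this story: a forward model that
generates realistic MSS-like traces under normal and rDC injection
programs, and the signal-processing pipeline that turns a trace into
intensity, noise, and S/N statistics.

## Forward model

**Sorption kinetics.** Each gas component $i$ sorbs into the receptor film
by first-order relaxation towards its partition equilibrium:

$$\frac{dq_i}{dt} = \frac{K_i\,c_i(t) - q_i}{\tau_i}, \qquad q_i(0) = 0,$$

where $c_i(t)$ is the delivered concentration (piecewise constant, set by
the active injection segment), $K_i$ a dimensionless partition coefficient,
and $\tau_i$ a sorption time constant in seconds. This is the simplest
model consistent with the observed transient-then-steady-state behaviour of
polymer-coated nanomechanical sensors, whose responses combine gas
diffusion into the layer with viscoelastic stress relaxation; both effects
are absorbed here into a single effective $\tau_i$ per component per film.
Films may assign every component its own $(K, \tau, g)$, so a component can
be given two effective modes by splitting it across two pseudo-components
if needed. Admissible $\tau$ defaults to $[0.05, 200]$ s, bracketing the
0.1–100 s range typical of such films.

**Transduction.** The film strain signal is the responsivity-weighted sum
$s(t) = \sum_i g_i q_i(t)$, expressed as a fractional resistance change,
and the four-piezoresistor Wheatstone bridge reads

$$V_\mathrm{out} = \frac{V_B}{4}\left(\frac{\Delta R_1}{R_1}
 - \frac{\Delta R_2}{R_2} + \frac{\Delta R_3}{R_3}
 - \frac{\Delta R_4}{R_4}\right).$$

How strain distributes over the four arms is a device property the readout
formula does not fix; the package defaults to the full-bridge pattern
$(+1, -1, +1, -1)\,s(t)$, giving $V_\mathrm{out} = V_B\, s(t)$, and exposes
the arm weights in `bridge_config()` for other patterns. The bridge
operation is the single point where volts become microvolts; everything
downstream works in μV. The default $V_B = -1.0$ V with negative
responsivities yields the positive-going odor responses typical of these
sensors.

**Disturbances.** Noise is additive and stationary: i.i.d. Gaussian noise
(default σ = 1 μV), a linear baseline drift (default 0.05 μV/s, emulating
the slow thermal baseline shift of the readout circuit), and optionally a
single sinusoid standing in for the non-Gaussian periodic undulations that
pump and valve electronics can impose (off by default, so the default
conditions stay in the Gaussian regime where the $1/\sqrt N$ and quadrature
laws are exact). Seeds are mandatory explicit inputs; the simulator never
touches the caller's global random state.

## Protocol conventions

An injection program alternates two gas lines every `interval_s` (default
5 s) for `total_duration_s` (default 120 s) at `sampling_rate_hz`
(default 100 Hz). Samples sit at $t = k/f_s$,
$k = 0 \dots T f_s$ inclusive (12 001 samples for the default run);
segments are half-open $[t_\mathrm{start}, t_\mathrm{end})$, and the sample
at a valve switch belongs to the incoming segment. Valve switching is
treated as instantaneous — the gas line's mixing and dead volume are not
characterised here; a dead time could be added later as a pure delay.

The schedule starts with Sample 2, so Sample 1 is first injected at
$t = 5$ s and its injections start at 5, 15, …, 115 s. A normal
measurement is the *same* valve schedule with the Sample 2 line delivering
clean carrier: it opens with carrier and injects the sample odor at the
same absolute times as the rDC run. This convention matters: the analysis
window (55–115 s) must begin at a Sample 1 injection start for *every*
measurement type, since the cycle origin anchors both the baseline
correction and the intensity statistic. An analysis cycle is
$[\,\text{S1 start}, \text{next S1 start}) = $ 5 s of Sample 1 followed by
5 s of Sample 2 (or carrier), placing the signal peak at local 5 s and the
noise fit window at 9–10 s.

Because the model is linear, the rDC trace is exactly the superposition of
the two normal traces with the Sample 2 response shifted into the opposite
phase; at steady state the rDC alternation amplitude equals the difference
of the two normal amplitudes. This identity (verified to $10^{-6}$ relative
in the tests) is the linear-model baseline: any genuinely nonlinear
co-sorption enhancement on real hardware would register as a deviation from
it. No such nonlinearity is modelled — its physical mechanism is unresolved
— so the package makes no attempt to reproduce hardware-specific intensity
magnitudes.

## Signal-processing pipeline

1. **Window** (`extract_window`): keep $t \in [55, 115)$ s — six full
   cycles recorded after the transient — and re-time from 0. The window is
   an explicit parameter; a convergence check (consecutive-cycle maximum
   difference against the mean cycle amplitude) can warn when the window is
   not yet at steady state, but never alters results.
2. **Segment** (`segment_cycles`): reshape into an $N \times M$ matrix
   (6 × 1000 at the defaults); concatenating rows reproduces the window
   bit-exactly.
3. **Baseline-correct** (`baseline_correct`): per cycle, subtract the first
   sample so each cycle starts at exactly 0 μV. Offsets from drift are
   removed; the within-cycle slope is deliberately retained (the
   straight-line fit in the noise estimator absorbs it).
4. **Average** (`average_cycles`): pointwise mean over the $N$ cycles.
5. **Noise** (`noise_level`): ordinary least squares line over the samples
   in $[9.0, 10.0)$ s — the last second of the cycle, where the response is
   nearly linear — and the noise level is the root mean square of the
   residuals. The divisor is the sample count $n$ (the literal RMS); the
   bias-corrected $n-2$ divisor is available as an option. The raw noise of
   a measurement is the mean of the per-cycle noise levels before
   averaging.
6. **Intensity** (`signal_intensity`): output at local 5 s minus output at
   0 s, using the single grid samples (no smoothing width is defined, so
   none is applied). After baseline correction this is just the 5 s sample.
7. **References**: the theoretical averaged noise is
   $\sigma_\mathrm{raw}/\sqrt{N}$ — the Gaussian averaging law (a statement
   of $1/\sqrt N$ proportionality; the division is by $\sqrt N$, not $N$) —
   and the theoretical noise of a difference of two independent traces is
   $\sqrt{\sigma_a^2 + \sigma_b^2}$, which is the $\sqrt 2$ penalty that
   makes differencing of normal measurements noisier than rDC at matched
   per-trace noise.
8. **S/N and aggregation**: $\mathrm{S/N} = |I| / \sigma_\mathrm{avg}$ per
   measurement; replicate statistics (`snr_summary`) are mean ± sample SD
   of the per-measurement values. The mean of ratios is reported, not the
   ratio of means — the two differ, and the per-measurement convention is
   what makes the SD meaningful. If a noise-free simulation yields exactly
   zero averaged noise, the summary reports the zero noise floor and flags
   it instead of an infinite S/N. No low-pass or moving-average filtering
   is applied anywhere: such filters would attenuate the fast sorption
   transients that carry most of the discriminative information.

**Steady-state detector.** `detect_steady_state` counts transient cycle
transitions: it reports the first transition whose consecutive-cycle
maximum difference falls below 5 % (≈ $e^{-3}$) of the first transition's
difference. Under the model's geometric decay with ratio
$e^{-10/\tau}$ this fires within $\lceil 3\tau/10 \rceil$ transitions for
any $\tau \le 30$ s. An absolute floor of $10^{-9}$ μV guards against
floating-point residue on noise-free traces.

## The synthetic study

`experiment_design()` encodes the benchmark design at desk scale: two
sources sharing a dominant base — humidity at concentration 100 (arbitrary
units) and two bulk VOCs at 10 — each with one distinct flavor component at
1, so the interferents outweigh the discriminating odorants by two orders
of magnitude (the constructor rejects designs violating this regime). Two
receptor channels with PPPO-like and PS-like selectivity use per-component
$\tau$ spanning 0.3–30 s and responsivities of a few $10^{-6}$ per sorbed
unit, sized so the normal-measurement response is ~100 μV while the
flavor-driven rDC signal is a few μV. The default Gaussian σ of 1 μV then
puts the raw single-cycle rDC S/N around 5: large enough to measure, small
enough that the benefit of averaging is visible. Six replicates of
{normal A, normal B, rDC(A, B)} are generated per channel, every trace with
its own seed derived deterministically from the design's base seed
(distinct by construction, checked at generation time), so regeneration is
bit-identical. These are generic, plausible values chosen once to exercise
the analysis — not a calibration to any real polymer or chocolate VOC
chemistry, whose per-component parameters are unknown.

What the generator does *not* emulate: non-Gaussian noise (unless the
undulation term is switched on), temperature and humidity physics, flow
dynamics and valve dead volume, film topography, and any nonlinear
co-sorption. Passing tests therefore demonstrate the correctness of the
protocol logic and the statistical pipeline under the stated model — they
do not certify performance on real hardware, where the deviations above are
exactly the interesting part.

## Numerical choices

* The kinetics are advanced with the exact per-segment exponential update
  $q(t) = Kc + (q_0 - Kc)e^{-(t - t_0)/\tau}$ on the sampling grid — no
  integrator tolerances; the tests cross-check against a stiff ODE solver.
* Traces serialise with time at 4 decimal places and output at 6
  significant digits; summary statistics at 4 significant digits. Reading
  back a written trace reproduces values at that precision, and
  write–read–write is byte-stable.
* Degenerate inputs fail loudly: non-dividing intervals, off-grid window
  boundaries, fit windows with fewer than 3 samples, mismatched grids in
  trace differencing, duplicated timestamps on read (with line numbers).
* Problem sizes in the tests and acceptance script — 200 Monte-Carlo trials
  per noise-law check, 6 replicates, 120 s runs at 100 Hz — were chosen as
  the smallest sizes at which the Monte-Carlo bands (5–15 % depending on
  the statistic) are comfortably stable.

## Known limitations

* Single-mode first-order kinetics per component; real films show
  stretched, multi-mode relaxation.
* The linear strain superposition cannot reproduce co-sorption
  enhancement effects; the pipeline can only *measure* a deviation from
  linear superposition, not generate one.
* The noise model is stationary; real baselines show slow non-linear
  wander beyond the linear drift term.
* Channels are processed independently; no cross-channel statistics are
  computed.
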