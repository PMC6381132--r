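---
title: "Strain modulation of impulse conduction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain modulation of impulse conduction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mecstrand)
```

`mecstrand` simulates and analyses mechano-electric coupling (MEC)
experiments in which a patterned strand of cardiomyocytes, grown on a
dielectric-elastomer actuator (DEA), is paced while defined uniaxial
strain cycles are applied to a central stretch zone, and impulse
conduction is read out from six extracellular electrodes. This vignette
is the package's own account of the models, the parameters that matter,
and the choices made where the design was open.

## The physical model

### Actuation

The actuator strain follows a cubic power law of the drive voltage,
$\varepsilon(V) = \varepsilon_{ref}\,(V/V_{ref})^3$ (Maxwell pressure
$\propto V^2$, plus one power of $V$ from dielectric thinning). The
defaults place 10% strain at 3.6 kV, with a hard 5 kV amplifier bound
treated as a configuration error rather than silent clipping. Driving
the voltage as $V_{max}\,(t/t_{ramp})^{1/3}$ therefore produces a strain
ramp linear in time — a constant-strain-rate stimulus. The two
compression zones flanking the stretch zone move with opposite sign at a
fixed coupling `k_c = 0.2` (the ~−2% / +10% pair), and are treated as
identical.

Viscoelastic creep is modelled with one exponential per transition:
the ramp attains `fast_fraction = 0.85` of the target, the rest creeps
in with `tau_on = 2` s; relaxation uses `tau_off = 4` s; and a small
residual accumulates geometrically over cycles (3% of amplitude,
halving each cycle), saturating within ~5 cycles. The time constants
are *placeholders shaped to the qualitative record* (85% during the
ramp, slower relaxation, early-cycle accumulation), not calibrated
values — the published record shows them only graphically. All four
parameters are exposed in `creep_params()`. Realized peak strain is
guarded at 1.2× target; exceeding it is an error.

The standard protocol is 10 s baseline + 10 cycles of 4.8 s (50% duty)
+ 10 s tail = 68 s, paced at 2.5 Hz throughout. Pacing stimuli sit on a
fixed 400 ms grid from $t=0$; ramp onsets are scheduled 100 ms after the
preceding stimulus, so the first post-ramp activation occurs 300 ms
after ramp onset — even the slowest 200 ms ramp is complete and the
strain quasi-static at every activation.

### The strand as a discrete cable

The strand (9.7 mm × 1.6 mm) is a chain of ~323 cells of resting length
30 µm. Per cell, a fraction `f_cyto = 0.29` of the axial resistance is
cytoplasmic and the rest gap-junctional. Under local strain
$\varepsilon$ the cytoplasm conserves volume (length ×$(1+\varepsilon)$,
cross-section ×$1/(1+\varepsilon)$), so its resistance scales as
$(1+\varepsilon)^2$ while gap-junctional resistance is
strain-independent; membrane (capacitance) per cell is conserved. Cable
theory then gives, across a uniformly strained segment,

$$\frac{\mathrm{ATD}(\varepsilon)}{\mathrm{ATD}(0)}
  = \sqrt{f(1+\varepsilon)^2 + 1 - f},
\qquad
\frac{\theta(\varepsilon)}{\theta_0}
  = \frac{1+\varepsilon}{\sqrt{f(1+\varepsilon)^2 + 1 - f}}
  \approx \frac{1+\varepsilon}{1+\alpha\varepsilon},$$

where $\alpha$ is the secant slope of the first expression — the
measurable, nearly-linear slope of fractional ATD modulation against
strain. Inverting the secant match at the maximal strain yields the
closed form $f = \alpha(2+\alpha\varepsilon)/(2+\varepsilon)$
(`invert_alpha_to_f()`), which maps $\alpha = 0.30$ at
$\varepsilon = 0.10$ to $f = 0.29$.

Two generators produce activation times:

* `kinematic_activation_times()` — closed-form path integrals over the
  zones using the law above; this is the fast generator used by the
  campaign runner.
* `simulate_propagation()` — an explicit-Euler discrete-cable
  integration with a two-variable membrane (cubic activation
  `k v(v-a)(v-1)`, slow linear recovery). The membrane is deliberately
  minimal: every analysed quantity depends only on upstroke timing, so
  ionic realism buys nothing here. By construction it has **no strain
  coupling**, so simulated ATDs depend only on the static strain at
  activation — the strain-rate independence that the analysis chain must
  (and does) report back. Axial resistance is calibrated once so the
  resting velocity is 324 mm/s (`calibrate_strand()`; velocity scales as
  the inverse square root of axial resistance, so calibration converges
  in two rescaling passes). The oracle-equivalence test shows the
  simulated ATD ratios match the closed form to < 0.1% for
  $\varepsilon \in \{-0.02, 0.05, 0.10\}$, and halving the cell length
  changes velocity by < 0.5%, so the 30 µm discretisation is not doing
  the work.

Electrodes are *material* points (cells stay attached under strain):
III/IV centres sit 10 µm outside the ±1.1 mm stretch-zone boundaries so
each 200 µm electrode straddles its boundary, giving a III–IV separation
of 2.22 mm and a resting III–IV conduction-time difference of
2.22/324 s = 6.852 ms. The stimulus-to-strand-edge latency is fixed at
5.5 ms — in the physical device the stimulation sites lie beyond the
recorded bar — which keeps the first electrode's downstroke clear of the
5 ms stimulation blanking; latencies cancel in every ATD.

### Electrogram synthesis

The extracellular beat (`apec_template()`) is defined through its first
derivative: a Gaussian negative lobe of amplitude −2.2 V/s and width
σ = 163 µs (this carries all timing information), a broader positive
lobe with 40% of the downstroke area placed 3.2 ms earlier, and a slow
recovery lobe returning the waveform to baseline. The peak-to-peak
amplitude equals the Gaussian drop $A\sigma\sqrt{2\pi} \approx 0.9$ mV.
The positive-lobe separation is larger than in a textbook biphasic
spike; it is chosen so the derivative inside the ±2 ms fitting window is
purely Gaussian, which is what makes the noiseless round trip exact to
< 0.1 µs. Templates are evaluated in closed form (Gaussian integrals),
so beats can be placed with sub-sample timing on the 20 kHz grid.

Records then receive, in order: stimulation-artifact leakage (bi-polar
rectangle, 2 ms), actuator coupling transients over each ramp, white
Gaussian noise (default 10 µV RMS — the published noise floor is not in
the available text, so this is a stated assumption and every test names
its noise level), AC coupling (bilinear one-pole high-pass,
τ_c = 8 ms; 1.6 s passes repolarisation-scale components), clipping at
±4 mV with a warning flag, and 6 µV quantisation. Rendering is
bit-reproducible under a fixed seed.

The 20 kHz sampling rate is a package choice (the source does not state
one): it makes the grid spacing 50 µs, so the microsecond-scale timing
precision demonstrably comes from the Gaussian fit, not the grid.

### The analysis chain

Blanking sets stimulation spans (5 ms) and actuator-ramp spans
(≥ 10 ms, never less than the ramp time) to background and excludes
them — plus a 4-sample guard on each side, because the blanked-to-live
discontinuity otherwise leaks a spike into the 5-point derivative
stencil.

Activation times come from a least-squares Gaussian fit
$-A\exp(-(t-\mu)^2/2\sigma^2)+b$ to the trace derivative in a ±2 ms
window around the derivative minimum. Numerical choices that matter:

* **Droop correction.** The AC high-pass superimposes ≈ 3% of $A$ as an
  asymmetric step centred on the lobe, biasing $\mu$ by ~6.6 µs. The
  bias is identical for every beat and cancels in ATDs, but it is easy
  to remove exactly: τ_c is acquisition metadata, so
  `trace_derivative()` inverts the bilinear high-pass before
  differencing.
* **Derivative stencil.** The five-point central difference
  $(x_{i-2}-8x_{i-1}+8x_{i+1}-x_{i+2})/12h$; its response is flat to
  fourth order over the downstroke bandwidth, so the fitted amplitude is
  unbiased (< 0.1%), where a quadratic Savitzky–Golay derivative of the
  same support would attenuate it by ≈ 3%.
* **Optimiser.** `minpack.lm::nls.lm` with an analytic Jacobian; start
  values $\mu_0$ = argmin, $A_0 = |min|$, $\sigma_0$ = 200 µs, bounded
  $\sigma \in$ [2 samples, 5 ms]. Formula-level `nlsLM`/`nls(port)` fail
  erratically on zero-residual synthetic beats. Fits with amplitude
  below 5× the robust derivative-noise estimate are rejected with a
  reason code; rejected beats keep their rows.
* **Derived features.** $t_{DS} = 5.77\,\sigma$ — the width multiple is
  a package convention making the default template report ~940 µs; the
  source never defines the downstroke duration, and its printed value is
  read as µs (printed unit "ms" is inconsistent with a −2.2 V/s, 0.9 mV
  signal). The fit error reported per beat is the standard error of
  $\mu$.

Under the stated conditions (0.9 mV beats, 10 µV noise, 20 kHz,
quantised) the per-beat activation-time scatter is ≈ 3.5 µs, and the
mean error over 1000 beats is < 1 µs.

ATDs are per-beat differences between electrode pairs (III–IV straddles
the stretch zone; I–III spans compression). Per cycle, the modulation is
the mean strained-phase ATD relative to the **last ATD of the preceding
relaxed phase** — renewing the reference each cycle is what makes the
estimate robust to creep accumulation; a global-baseline variant exists
to quantify exactly that bias. The strain abscissa for the slope fit is
the *effective* strain: mean realized strain over the strained-phase
beats minus realized strain at the reference beat, taken from the
(calibrated) strain trace — as in the experiment, where strain is
calibrated optically rather than assumed equal to its target.

The slope $\alpha$ is fitted through the origin (the law passes through
(0,0) exactly; a with-intercept diagnostic variant exists), per ramp
time and pooled. Rate independence is a regression of $\alpha$ on
maximal strain rate with an "independent" verdict when the CI covers
zero. Strength–duration data are fitted to the Lapicque hyperbola
$I = I_{rh}(1+t_{ch}/t)$, linear in the parameters after $u = 1/t$,
with $1/I^2$ weights because threshold scatter is multiplicative.

## What the generator does and does not emulate

The synthetic data reproduce: the protocol bookkeeping (170 beats per
electrode over 68 s, 25 baseline and 12 per-cycle determinations),
biphasic beats of realistic amplitude/downstroke, AC coupling,
quantisation, white noise, stimulation and actuator artifacts, creep
with per-cycle accumulation, and strain-scaled conduction with a chosen
resistance partition. They do **not** emulate: correlated or
non-stationary noise, electrode-to-electrode template variability,
baseline wander from motion, repolarisation waves (only the short-τ_c
regime is analysed), beat-to-beat biological variability, or any real
strain coupling of membrane kinetics. Passing tests therefore show that
the *analysis chain* recovers the generator's ground truth under
realistic noise — they do not certify performance against biological
confounds absent from the generator.

A consequence worth stating: the full campaign recovers a pooled slope
of ≈ 0.294–0.295 from a generator built with $f = 0.29$ (exact secant at
10%: 0.300). The shortfall is measurement physics, not an estimator
bug — the origin-constrained secant of a convex law pooled over
sub-maximal effective strains (creep keeps realized strain at ~89–93% of
target) is smaller than the $\varepsilon=0.10$ secant, and 0.9% of the
III–IV path lies in the compression zones.

## Problem sizes and budgets

The package's test and reproduction runs use: single 68 s protocols at
20 kHz × 6 electrodes (≈ 8 × 10⁶ samples, ~1000 Gaussian fits, seconds);
the full campaign of 6 amplitudes × 5 ramp times (30 protocols, ~31 000
fits, a few minutes); cable integrations at dt = 2 µs over ~35 ms sweeps
(323 cells). These sizes were chosen so every documented quantity is
recomputed from scratch in minutes on a single core while keeping the
Monte-Carlo assertions well-powered.

## Known limitations

* Creep time constants are qualitative placeholders (see above);
  conclusions that depend on the exact creep shape should rescale them
  against a measured strain record.
* The compression zones are treated as identical and linearly coupled
  (`-k_c` × stretch); real devices show slight asymmetry.
* The membrane model has no refractoriness to speak of beyond its slow
  recovery variable; it is calibrated for 1:1 capture at 2.5 Hz and
  upstroke timing only, and is not suitable for APD or restitution
  questions.
* `fit_velocity()` assumes a single uniform wavefront between the
  stimulated end and the last electrode; fractionated or re-entrant
  activation is only flagged (`discontinuous`), not analysed.
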