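---
title: "Models and methods behind durakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind durakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(durakit)
```

durakit collects the quantitative methods used to characterize and analyze
transparent surface micro-electrocorticography (μECoG) arrays of the
artificial-dura type: micron-scale metal electrodes embedded in a
PDMS/Parylene C laminate that replaces the native dura, records field
potentials and multi-unit activity, stimulates, and stays optically
transparent for imaging and optogenetics. This vignette explains the models,
their assumptions, the tunable parameters, and the design choices where the
underlying procedure left room for judgment.

## Electrode model and impedance analytics

The electrode-electrolyte interface is simulated as a Randles-type
equivalent circuit: the solution (access) resistance $R_s$ in series with
the charge-transfer resistance $R_{ct}$ in parallel with a constant-phase
element, $Z_{CPE} = 1/(Q (j\omega)^\alpha)$, $\alpha \in (0, 1]$. The form
is an implementation choice — a standard one for metal and PEDOT:PSS-coated
microelectrodes — not a claim about any particular fabricated device; its
purpose is to provide impedance spectra and stimulation transients with
exactly known ground truth for testing the analytics.

From a measured or simulated spectrum the package computes:

* two-point impedance $Z = V_{ref} / I_c$ (`impedance_from_vi()`),
* Johnson thermal noise $V_{rms} = \sqrt{4 k_B T R \Delta f}$ with
  $R = |Z|\cos\theta$ the real part (`thermal_noise_rms()`; defaults
  $T = 300$ K, $\Delta f = 30$ kHz, a typical broadband front-end rate),
* theoretical SNR $= 20\log_{10}(V_{signal}/V_{noise,rms})$ (`snr_db()`).
  Note that a 150 μV signal against a 3.4 μV\(_{rms}\) floor is $\approx$
  33 dB under this definition; claims of much larger values for such
  inputs do not follow from the formula,
* population summaries (mean, sample SD, CV) at a query frequency with a
  1% nearest-frequency tolerance (`impedance_summary()`), and channel
  yield with configurable working-channel bounds, default
  1 kΩ–1 MΩ at 1 kHz (`channel_yield()`); no standard definition of
  "working" exists, so the bounds are explicit parameters,
* electroplating charge cutoffs, `density × π(d/2)^2` with a default
  density of 1 μC/μm² (`deposition_charge_cutoff()`). The exact area of a
  20 μm disc is 314.16 μm², so the truncated integer report is 314 μC;
  a convention that rounds up would print 315.

## Stimulation transients and charge-injection capacity

A charge-balanced burst (default: 5 biphasic pulses, 0.6 ms per phase,
200 μs interphase gap, cathodic first) is applied to the circuit and the
reference-electrode voltage is synthesized as
$v(t) = E_{ipp} + i(t) R_s + v_{int}(t)$. For $\alpha = 1$ the interface
term is exact per-sample exponential RC charging; for $\alpha < 1$ the
interface impedance is approximated by a series (Voigt) chain of parallel
RC branches. The chain uses 7 branches with log-spaced time constants
extended one decade beyond the stimulation band and magnitude-weighted
least squares with backward elimination of negative branches; 5 branches
leave up to ~10% spectral error over three decades, 7 stay within ~3%,
which is what the 2% pipeline tolerances need with margin. A blocking
interface ($R_{ct} = \infty$, $\alpha = 1$) is handled exactly as an ideal
integrator. The default simulation rate of 1 MHz makes pulse edges
single-sample steps, matching the assumption that access voltage appears
near-instantaneously.

The analysis pipeline mirrors the standard voltage-transient procedure:

1. first derivative by central differences (`central_difference()`),
2. edge detection at derivative extrema (`detect_pulse_edges()`). The
   threshold is adaptive — 10× the median absolute baseline derivative —
   plus a steepness floor of 30% of the peak derivative, because access
   steps are by assumption the steepest events in the trace; without the
   floor, slow intra-pulse charging on low-noise traces merges whole
   pulses into single "edges",
3. polarization bias $E_{ipp}$ as the pre-pulse baseline mean
   (`estimate_eipp()`), subtracted from the trace,
4. access-voltage steps measured between the samples flanking each edge
   (guard of ±1 sample, configurable) and removed; what remains is the
   continuous interface polarization $V_{\mu E}$, whose extrema are
   $E_{mc}$ and $E_{ma}$ (`isolate_interface_voltage()`),
5. water-window compliance on the closed interval $[-0.9, 0.6]$ V by
   default, the usual PEDOT:PSS bounds (`check_water_window()`),
6. charge-injection capacity $Q_{inj} = I \cdot pw_c / GSA$ in mC/cm²
   (`charge_injection_capacity()`), evaluated at the largest compliant
   amplitude of a ramp (`cic_ramp()`). With a 50 μA, 0.6 ms pulse the
   formula gives 9.55 mC/cm² for a 20 μm disc and 2.39 mC/cm² for 40 μm;
   published figures for comparable electrodes sometimes assume a larger
   effective area, so reported values below the 20 μm figure are not
   inconsistent with the formula.

On $\alpha = 1$ simulations the pipeline recovers $I R_s$ and the
closed-form charging extrema within 2%, which is the tolerance the test
suite enforces.

## Optics

Normal-incidence Fresnel reflectance $((n_1-n_2)/(n_1+n_2))^2$ gives
5.88% for a Parylene C (n = 1.64) surface against air and 1.09% against
water/CSF (n = 1.33) — a 4.79% difference, which is why such devices
transmit better implanted than on the bench. Stack transmission is the
product of $(1-R)$ over successive interfaces, deliberately ignoring
multiple partial reflections (no Fabry–Pérot terms) and, optionally,
applying Beer–Lambert attenuation per layer. Spectrometer processing
follows the dark/reference/sample convention
$T(\lambda) = (S-D)/(R-D)$ with linear interpolation onto the sample grid
and masking where the dark-corrected reference is non-positive.

Optical access of a layout — the fraction of the circular window not
covered by opaque metal — is the area of the *union* of all features
(electrode discs, trace capsules, taper polygons) intersected with the
window disc. Traces are modelled as capsules (all points within half a
width of the polyline), which keeps joins gap-free and coincides exactly
with a distance-to-segment test. The union area is computed by reducing
every feature to exact x-intervals on each of 4001 horizontal scanlines,
taking the exact 1-D interval union per scanline, and integrating by the
trapezoidal rule; the only approximation is the y-discretization, whose
error is far below the Monte-Carlo confidence band used to validate it
(a 10⁶-point rasterization with independent point-in-feature tests).
`ignore_traces_narrower_than` removes traces at or below a width
threshold before the computation, modelling the observation that ~10 μm
traces are effectively transparent to imaging systems focused below the
device — so effective optical access exceeds apparent transparency, and
raising the threshold can only increase access.

## Bilayer mechanics

Three analytic surrogates describe the laminate:

* Voigt effective modulus $\sum E_i t_i / \sum t_i$: 250 μm of PDMS
  (2 MPa) plus 10 μm of Parylene C (2.8 GPa) gives 109.62 MPa, inside the
  60–110 MPa range quoted for native dura,
* composite flexural rigidity by the transformed-section method with
  plane-strain weighting $E_i/(1-\nu_i^2)$ about the computed neutral
  axis (validated against brute-force through-thickness integration),
* center deflection of a clamped, uniformly loaded circular laminate from
  the Föppl-type interpolation
  $P R^4 / (64 D) = w_0 (1 + 0.488 (w_0/t)^2)$, solved for the positive
  root. The cubic coefficient 0.488 is the classical clamped-immovable-edge
  value; in the small-pressure limit the pure-bending
  $w_0 = P R^4/(64 D)$ is recovered within 1%.

This replaces hyperelastic finite-element modelling, so the published
deflection figures for specific devices (≈1.8 mm vs ≈0.3 mm for
250/10 μm vs 220/40 μm stacks at unspecified CSF-range pressure) are
treated as an ordering to reproduce qualitatively, not values to match:
the load behind them is not stated, and a linear-plate surrogate is not a
Neo-Hookean FEM. Default Poisson ratios are assumptions: 0.49 for PDMS
(nearly incompressible), 0.40 for Parylene C. Inputs are MPa/μm/mm/Pa as
declared per field; all internal computation is SI.

## Synthetic recordings

`generate_lfp_session()` builds trial-structured multichannel surface
recordings with fully known ground truth: per channel a $1/f$-shaped
Gaussian background (slope 1 by default, the typical LFP spectral decay),
power-line components at 60/120/180 Hz, optional decaying-exponential
artifacts, and event-locked evoked effects. An evoked effect is an
additive band-limited Gaussian component gated to the response window and
scaled so that the *measured* in-window band power is `power_multiplier`
times the channel's baseline band power. The scale is calibrated by
passing the gated component through the same analysis band-pass used for
measurement, so filter skirts and the gating's spectral splatter are
included; without this calibration a nominal ×2 effect measures as ~×1.6.
Everything planted is returned as ground truth, and identical seeds give
bit-identical sessions.

`generate_spiking()` plants Poisson spike times (refractory period
enforced by dead-time insertion, default 1 ms) carrying a trough-dominant
biphasic template over Gaussian background noise, scaled so peak-to-trough
amplitude over background SD matches the requested SNR. The template's
trough carries 90% of the excursion, as extracellular waveforms do; a
symmetric template at 20 dB SNR would sit too close to a −6 SD threshold
for reliable detection, which is a property of thresholds, not of the
detector.

What the generator does *not* emulate: volume conduction and
channel-to-channel correlation, non-stationary background, behaviorally
realistic trial timing, spike-waveform drift, or electrode-specific gain.
Passing tests therefore demonstrate that the analysis recovers what it
claims from data matching its assumptions — not performance on any real
recording.

## Analysis pipeline

* **LFP extraction**: zero-phase (forward–backward) 8th-order Butterworth
  low-pass at 250 Hz, 2nd-order notches at 60/120/180 Hz (width $f/30$),
  then decimation to 1 kHz. An 8th-order low-pass is used because a
  4th-order one attenuates a 300 Hz component by only ~14 dB
  forward–backward, which is too little separation from the spiking band;
  8th order gives 26 dB and is numerically stable at these normalized
  frequencies. All filtering uses odd-reflection padding to suppress edge
  transients.
* **Band power**: band-pass (4th-order Butterworth, zero-phase) then
  sum of squares divided by duration in seconds — so a unit in-band
  sinusoid gives $f_s/2$ regardless of duration. Named bands follow the
  common μECoG conventions (`band_set()`): theta 4–8, alpha 8–15,
  beta 15–30, gamma 30–70, low/high gamma 30–59/60–150 Hz. The gamma
  30–70 band and the 30–59/60–150 split coexist because different
  paradigms conventionally use different partitions; both are provided.
* **Task-vs-baseline mapping** (`power_change_map()`): per-trial,
  per-channel band power in task and baseline windows; paired t-test per
  channel, Bonferroni over channels (family-wise 0.05). Bonferroni is
  applied within one analysis, not across analyses. The spatial map
  interpolates channel values with inverse-distance weighting.
* **Multitaper spectrograms** (`mt_spectrogram_z()`): DPSS tapers computed
  from the symmetric tridiagonal formulation, time-bandwidth 3 with 5
  tapers by default; per-trial spectrograms averaged, then z-scored per
  frequency against the baseline-interval columns.
* **Spike analysis**: high-pass at 250 Hz; background SD by the robust
  estimator median(|x|)/0.6745 so the spikes themselves do not inflate
  the threshold; detection at −6 robust SDs with 1 ms refractory;
  trough-aligned snippets; K-means sorting on the first 3 principal
  components under a fixed seed; empirical SNR as mean-waveform
  peak-to-trough over background SD (trough-only is available — the
  amplitude convention is configurable because no single one is
  universal).
* **Artifact rejection** (`artifact_reject()`): z-normalize per analysis
  period (normalization scope is configurable; per-period is the
  default), mask |z| > 10 with an optional guard margin.
* **Stimulation blocks** (`stim_block_analysis()`): band-pass, artifact
  mask, normalize to the first baseline period, power per period as
  sum-of-squares/duration; spontaneous change = baseline2 − baseline1,
  induced change = post − baseline1; one-sample and paired t-tests across
  blocks at the network level, Bonferroni per-channel.
* **Evoked windows** (`evoked_window_test()`): 100 ms pre / 200 ms post
  band power per trial, each normalized by its own duration, two-sample
  t-test per channel.
* **Impedance normalization** (`impedance_normalized_response()`):
  averaged z-band responses divided by per-channel impedance magnitude,
  removing electrode-gain differences before spatial comparison.

Windows are half-open `[start, end)` in seconds, event timestamps are
authoritative, and every stochastic step takes an explicit seed.

## Problem sizes used in validation

The test suite exercises the full pipeline at desk scale: 32 channels ×
800 one-second trials at 1 kHz for planted-effect recovery (the planted
channel set must be recovered exactly); 200 replicate null sessions
(16 channels, 20 trials) for the family-wise error bound
0.05 + 2 × binomial SE; 30 s of 30 kHz data for spike recall/precision
(≥ 0.95 at 20 dB) and SNR round-trip (±1 dB); 10⁶ Monte-Carlo points
against the scanline geometry (agreement within 3 binomial SEs). These
sizes were chosen to make the statistical bounds meaningful while keeping
a full run in the low minutes.

## Known limitations

* The equivalent circuit has no Faradaic nonlinearity, temperature
  dependence, or diffusion (Warburg) element; CIC estimates are therefore
  circuit-model statements, not electrochemical safety guarantees.
* The optical model is normal-incidence and incoherent; no etalon
  interference, scattering, or angled-ray geometry.
* The mechanics surrogate is linear-elastic with a scalar stretching
  correction; large-strain hyperelastic behavior of thick PDMS is out of
  scope.
* The statistical procedures are the field's standard t-test recipes; no
  hierarchical correction across analyses is attempted, matching common
  practice rather than improving on it.
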