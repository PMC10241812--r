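---
title: "Comb-based parallel interrogation of a micro-ring ultrasound array: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comb-based parallel interrogation of a micro-ring ultrasound array: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dofcpat)
```

# The system being simulated

A photoacoustic tomography (PAT) receiver built from 15 micro-ring
resonators on one bus waveguide, read out *in parallel* by a digital
optical frequency comb (DOFC) through a single laser and a single coherent
receiver. Acoustic pressure elasto-optically shifts each ring's resonant
frequency; a comb of closely spaced optical tones samples the whole array
transmission spectrum once per OFDM frame, so every ring's resonance — and
hence every element's pressure waveform — is recovered from one time
series. This package simulates every stage of that chain at desk scale,
plus the downstream image formation, so the processing can be tested
without hardware.

# Models, stage by stage

## Ring transmission

Each ring is a symmetric Lorentzian dip in amplitude transmission,

$$T_i(f) = 1 - d_i\,\frac{(\Gamma_i/2)^2}{(f - c_i)^2 + (\Gamma_i/2)^2},
\qquad \Gamma_i = \frac{f_\mathrm{carrier}}{Q_i},$$

with $d_i$ the dip depth (default 0.9 — deep but not total extinction;
per-ring depths are not published), $Q_i \in [5,7]\times 10^5$ (the
characterized range; we spread them linearly over the array), and
$f_\mathrm{carrier} = c/1550\,\mathrm{nm}$. Rings on one bus combine
multiplicatively; crosstalk beyond spectral overlap (coupled-mode or Fano
asymmetry) is not modeled, matching the Lorentzian fitting model the
demodulator assumes. Under pressure $p_i$ the dip center moves to
$c_i + S\,p_i$ with $S$ the pressure sensitivity.

**Sensitivity `sensitivity_hz_per_pa`.** No published value exists, so it
is a free calibration parameter, default $10^4$ Hz/Pa. What is physically
anchored is the *ratio* of receiver noise to sensitivity: the default noise
level was calibrated once (see below) so the parallel-mode pressure noise
floor matches the 36.9 Pa-in-20-MHz noise-equivalent pressure (NEP) scale
of the hardware. With this choice, kPa-scale photoacoustic pressures map to
10--100 MHz dip shifts, comfortably inside the ±830 MHz tracking window at
1.66 GHz ring spacing.

## Resonance layout and capacity

`assign_resonances()` reproduces the post-tuning state: centers ordered
with ring label and equally spaced (1.66 GHz default) about the band
midpoint, with an edge margin of half a linewidth per side as a guard
against demodulation edge effects. Capacity follows the allocation
argument, `floor(bandwidth / spacing)`: each ring occupies one spacing slot
of spectrum, giving 24 rings in 40 GHz at 1.66 GHz, or 200 rings at a
200 MHz allocation. Note a pure span argument ($(n-1)\times$ spacing) would
admit one more ring; we follow the allocation rule so the layout
constructor and the capacity arithmetic agree. The occupied span of 15
rings is $14 \times 1.66 = 23.24$ GHz; the ~24.9 GHz figure quoted for the
physical device includes tuning margins, and both numbers are exposed
rather than reconciled.

## The comb

One OFDM frame is `n_subcarriers = 1536` complex baseband samples at
`dac_rate_hz = 60 GS/s`: tooth spacing $\Delta f =$ 60 GHz/1536 =
39.0625 MHz, frame period 25.6 ns. Teeth of unit magnitude populate the
40 GHz band symmetrically about the carrier; the DC bin is zeroed
(carrier-suppressed double sideband, modeled at complex baseband rather
than through a modulator transfer function). Subcarrier phases are not
published and only affect the crest factor, so the default is the
deterministic Newman quadratic schedule, which keeps the peak-to-average
power ratio below 4 with no RNG; a seeded pseudo-random schedule is
available. No guard intervals or cyclic prefix are used. Fiber dispersion,
modulator nonlinearity and laser phase noise (cancelled in hardware by a
matched delay line) are not modeled.

## Interrogation and noise

The per-ring Nyquist limit after demodulation is $\Delta f/2 =$ 19.53 MHz,
so over one 25.6 ns frame a ring's pressure completes well under half a
cycle; the simulator therefore holds pressure constant within each frame
(quasi-static approximation) and multiplies each tooth by the array
transmission at its frequency. The coherent receiver — in hardware a local
oscillator, EDFA, optical filter and oscilloscope — is abstracted into one
gain plus additive complex white Gaussian noise on the measured samples,
parameterized relative to the frame RMS (`noise_spec$sigma_rel`).

**Noise calibration.** `calibrate_receiver_noise()` runs a noise-only
interrogation and scales `sigma_rel` linearly so the recovered pressure
floor matches the NEP target. The shipped default, `sigma_rel = 0.00436`,
is the value this loop returns for the default 15-ring array and full
comb against the 36.9 Pa / 20 MHz parallel-mode target; it was fixed once
and is not adjusted per experiment.

## Demodulation and dip tracking

Each frame is Fourier transformed and each tooth normalized by the
no-array reference frame (known analytically in simulation; measured in
hardware), yielding the transmission spectrogram. Dip tracking exploits an
exact algebraic property: for a single Lorentzian dip the reciprocal
deficit $1/(1-T(f))$ is an *exact quadratic* in $f$, so a weighted
quadratic least-squares fit over the window teeth gives the center in
closed form — machine-precision at zero noise, no iteration, and it
vectorizes over frames (the design matrix is frame-invariant). Before
fitting, the window transmission is divided by the other rings' null-case
dips so only the tracked ring's Lorentzian remains, to first order.
Weights are $L_0^4$ with $L_0$ the null-case deficit, the variance
weighting appropriate for the reciprocal transform; they are computed from
the tuned line shape, which is accurate for shifts up to about one
linewidth. An optional Levenberg–Marquardt refinement
(`fit_dips(refine = TRUE)`, via minpack.lm) polishes each frame when
shifts approach the window edge; it is off by default because the closed
form is already exact in the operating regime and an order of magnitude
faster.

Frames whose fitted center leaves the ±spacing/2 window are flagged and
interpolated from neighbours; if more than 25 % of a ring's frames are out
of window a tracking error naming the ring is raised (a drifted dip is a
configuration problem, not data).

Tooth values are magnitude-normalized by default (complex ratios are
supported); hardware practice is unstated, and magnitude is the more
robust choice under residual phase error.

## Direct (single-ring) interrogation

Wideband characterization needs bandwidth far above $\Delta f/2$, so the
single-sensor mode models CW edge detection: the laser parks on the dip
flank and transmission follows the pressure-shifted Lorentzian at the full
acoustic sampling rate. The default bias offset is $\Gamma/(2\sqrt3)$ from
center — the true maximum-slope point of a Lorentzian flank, where the dip
sits at 3/4 depth. (The half-depth point at $\Gamma/2$, sometimes quoted
as optimal, has slope $d/\Gamma$ versus $3\sqrt3 d/(4\Gamma)$ at the
inflection — about 23 % worse; the package's slope-sweep test verifies the
argmax.)

## Acoustic forward model

Sources and sensors are coplanar (as in the physical setup) but spreading
is spherical ($1/r$). Each absorber contributes, in the frequency domain,
its temporal signature × the sensor band-pass × the angular weight at its
incidence angle × attenuation × the time-of-flight phase × $1/r$.
Signatures: `gaussian_derivative` (bipolar pulse from Gaussian heating,
FWHM default 6.5 ns — the imaging laser's pulse width) for imaging
phantoms; `delta` for impulse-response characterization (the recorded
waveform then *is* the sensor kernel, as the hardware characterization
assumes); `n_shape` (the analytic N-wave) for finite-radius spheres. The
bipolar signature matters for imaging: universal back-projection's
derivative term expects a physical photoacoustic pulse, and with it a
noiseless full-view point reconstruction localizes to a few microns, while
an even (delta-through-kernel) pulse leaves a small radial bias.

The sensor magnitude response is a Gaussian in frequency truncated at DC,
parameterized by center (60 MHz) and −6 dB bandwidth (175 MHz) — the two
characterized numbers. Its −3 dB width (~141 MHz) is then a model
consequence; the separately quoted 115 MHz figure is carried as the
`bw_3db_hz` field for the closed-form axial-resolution estimate only. The
angular response is a spatial-aperture sinc whose effective width is
calibrated so the gain is exactly −3 dB at ±30° for 25 MHz; the implied
~53 µm aperture is commensurate with the 40 µm ring. Attenuation is an
optional power law (dB cm⁻¹ MHz⁻ʸ), off by default.

Acoustic sampling defaults to 500 MS/s for characterization-grade
simulation; comb-mode runs can brick-wall low-pass the records at
$\Delta f/2$ before decimating to the frame grid (`band_limit = TRUE`),
the anti-alias step of real DOFC acquisition, or instead warn/error on
out-of-band content (`on_alias`).

## Phantoms

Figure-8 hot spot (Gerono lemniscate trajectory), moving microsphere
(200 µm sphere, constant 4.8 mm/s), three interleaved hairs (line sources
rasterized to points), and a seeded recursive branching skeleton standing
in for leaf veins. The published experiments do not give the exact '8'
parameterization or leaf geometry, so these are qualitative, synthetic
stand-ins: deterministic per seed, with the study-relevant parameters
(sphere speed, hair count/crossing, trajectory period) explicit.

## Reconstruction

Universal back-projection accumulates
$b(r_0, t) = 2p(r_0,t) - 2t\,\partial p/\partial t$ at
$t = |r - r_0|/v$ per pixel and detector, with uniform weights per
detector (linear/static) or per angle (rotational; the exact solid-angle
weighting for arbitrary surfaces is out of scope). Temporal derivative by
central differences, fractional delays by linear interpolation, rotational
steps compounded coherently in the sample frame. The signed reconstruction
is stored; the analytic-signal envelope (`envelope_image`) is applied for
display and metrics. One caution established during development: the
point-spread function of a 175 MHz sensor oscillates on a ~17 µm scale, so
the default 25 µm pixels undersample it — peak-based metrics should use
`peak_position()` (sub-pixel parabolic refinement) or a finer grid, and
width metrics the envelope. Note the envelope FWHM is *wider* than any
single oscillation lobe (lobes are set by the ~90 MHz effective center
frequency, the envelope by the bandwidth); it is the statistic the
measured resolution figures refer to.

## Metrics

* `cnr()`: $20\log_{10}(\mathrm{peak}/\sigma_\mathrm{bg})$ over disjoint
  physical rectangles.
* `cnr_gain_mc()`: the element-number enhancement property. With equal
  per-sensor signal and iid noise, the linear CNR ratio of the 15-element
  coherent mean over the average single element is $\sqrt{15} = 3.87$. The
  Monte-Carlo uses exactly that fixture (equal pulses at the correct
  per-sensor times of flight), reads peaks at the known target pixel of
  envelope images, and averages the single-element reference over all 15
  elements, which makes $\sqrt N$ exact in the noise-dominated-background
  limit; 50 seeds give ≈3.75 (small residual bias from the envelope of
  noise). Expressed as $10\log_{10}$ of the linear improvement — the
  convention under which the hardware's 5.51 dB figure corresponds to
  $\sqrt{15} \approx 5.9$ dB — this is ≈5.7 dB. (Under the package's
  20 log CNR definition the same ratio is 11.5 dB; the two conventions
  coexist in the literature and we report both bases explicitly.)
* `estimate_speed()`: amplitude-weighted centroid of above-half-maximum
  pixels per frame, linear fit of centroid versus time.
* `profile_fwhm()`: envelope FWHM along a grid line with interpolated
  half-maximum crossings.

## Characterization pipeline

`time_gate` (hard or raised-cosine) isolates the first arrival;
`frequency_response`/`bandwidth_at_db` measure the contiguous band around
the spectral peak with interpolated edges (center frequency reported as
the −6 dB band centroid; secondary lobes ignored); `angle_map` converts a
linear sweep past a fixed source into frequency-versus-angle response,
compensating the known $1/r$ spreading so the map reflects the sensor
alone, with `acceptance_contour` interpolating the −3 dB angles; `nep`
divides a Welch amplitude spectral density (Hann segments, overlap 0.5,
segment count configurable — the estimator is not specified by the
hardware work) by the end-to-end sensitivity and integrates over the band.
The printed density bound (2.2 mPa/√Hz) and integrated NEP (7.1 Pa /
20 MHz) of the hardware imply a non-flat density whose shape is not
tabulated; they are treated as independent calibration anchors, not
derived from one another.

# Problem sizes and reproducibility

The shipped tests and the acceptance script use: 2048 frames of the full
1536-subcarrier comb for the three-ring round trip; 512 noise-only frames
of the 15-ring array for the noise floor; a 60-step full-view rotation and
25 µm, 4×4 mm grids for localization; a 161-position ±8 mm scan for the
partial-aperture comparison; 50 noise seeds for the CNR Monte-Carlo. These
sizes were chosen so the whole pipeline (including every stochastic check)
runs in about a minute while leaving each estimator's Monte-Carlo error
well inside its assertion margin. Every stochastic stage draws from an
explicit seed recorded in its output; seeded helpers save and restore the
caller's RNG state.

# What passing tests do and do not show

The synthetic generator reproduces the *structure* of the measurement
chain — Lorentzian dips on a multiplicative bus, comb sampling, coherent
detection noise, band-limited acoustic propagation with directivity — with
parameters matching the characterized hardware where published. It does
not reproduce hardware non-idealities: non-Lorentzian line shapes,
inter-ring optical crosstalk, laser drift, modulator nonlinearity,
heterogeneous sound speed, or the frequency-dependent attenuation of real
tissue. Consequently, passing round-trip and property tests validates the
*processing* (demodulation, tracking, reconstruction, metrics) and the
self-consistency of the forward model, not the absolute performance of any
physical device; the hardware's measured numbers (50.4/43.6 µm measured
resolutions, 5.51 dB CNR gain on leaf data, 2.2 mPa/√Hz density) enter
only as calibration anchors or bracketing checks.

# Known limitations

* The dip-fit weights come from the null-case line shape; accuracy
  degrades for shifts beyond about one linewidth (the window guard catches
  gross drift).
* Neighbour-tail compensation is first order (null-case division), leaving
  ~0.5 % crosstalk at 1.66 GHz spacing and kPa drive levels.
* The 2D-plane forward model with 3D spreading ignores out-of-plane
  response.
* Rotational UBP assumes the rotation center is known exactly.
* No model-based or iterative inversion; no sound-speed autofocus.
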