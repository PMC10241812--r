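# dofcpat

Desk-scale simulator and signal-processing toolkit for **parallel
interrogation of a micro-ring ultrasound sensor array with a digital
optical frequency comb (DOFC)**, and for the downstream **photoacoustic
tomography (PAT)** reconstruction.

## The problem

PAT needs many ultrasound detectors read out simultaneously. A chip with
15 micro-ring resonators on one bus waveguide can do this optically: each
ring is a narrow Lorentzian dip in the bus transmission

T_i(f) = 1 − d_i (Γ_i/2)² / ((f − c_i)² + (Γ_i/2)²),  Γ_i = f_carrier / Q_i,

and acoustic pressure shifts its resonance, c_i → c_i + S·p_i. A digital
frequency comb — an OFDM frame of 1536 subcarriers at 60 GS/s, tooth
spacing Δf = 60 GHz/1536 = 39.0625 MHz — samples the whole transmission
spectrum once per 25.6 ns frame through a single laser and a single
coherent receiver. Per frame, an FFT recovers every tooth; a Lorentzian
fit per ring tracks each dip center; the shift divided by the sensitivity
is that element's pressure waveform, sampled at Δf with usable bandwidth
Δf/2. Universal back-projection,

b(r₀, t) = 2 p(r₀,t) − 2 t ∂p/∂t evaluated at t = |r − r₀|/v,

then forms images over rotational, static, or linear-scan apertures.

This package implements that whole chain — array model, comb synthesis,
coherent detection with calibrated noise, demodulation and resonance
tracking, a band- and angle-filtered acoustic forward model with synthetic
phantoms, UBP imaging, and the sensor-characterization pipeline
(bandwidth, acceptance angle, noise-equivalent pressure, closed-form
resolution and capacity estimates) — so every processing stage can be
tested without hardware. It is aimed at researchers developing or
validating comb-based array readout and PAT reconstruction code.

## Worked example

Interrogate a 3-ring array with the full 1536-subcarrier comb for 2048
frames (52.4 µs), drive each ring with a distinct band-limited tone
(10 kPa amplitude, all below the Δf/2 = 19.53 MHz detection limit), and
recover the waveforms:

```r
library(dofcpat)

spec <- comb_spec()                                  # 1536 @ 60 GS/s, 40 GHz
cat(sprintf("tooth spacing: %.4f MHz\n", tooth_spacing(spec) / 1e6))
cat(sprintf("capacity at 1.66 GHz spacing: %d rings\n",
            max_rings_by_spacing(40e9, 1.66e9)))
cat(sprintf("FWHM at Q=7e5: %.1f MHz (%d comb teeth)\n",
            fwhm_from_q(7e5) / 1e6,
            sampling_points_in_fwhm(fwhm_from_q(7e5), tooth_spacing(spec))))

arr  <- assign_resonances(3, 1.66e9, c(-20e9, 20e9)) # ordered, equispaced
comb <- synthesize_comb(spec)
frate <- tooth_spacing(spec)                         # frame rate = Δf
t <- (0:2047) / frate
inject <- rbind(1e4 * sin(2 * pi * 3.0e6 * t),
                1e4 * sin(2 * pi * 7.5e6 * t),
                1e4 * sin(2 * pi * 14e6  * t))
attr(inject, "fs_hz") <- frate

meas  <- interrogate(arr, inject, comb, noise_spec(seed = 1))
waves <- fit_dips(demodulate_frames(meas), arr)
for (i in 1:3)
  cat(sprintf("ring %d: correlation %.4f, recovered RMS %.0f Pa\n", i,
              cor(waves$pressures_pa[, i], inject[i, ]),
              sqrt(mean(waves$pressures_pa[, i]^2))))
```

Output:

```
tooth spacing: 39.0625 MHz
capacity at 1.66 GHz spacing: 24 rings
FWHM at Q=7e5: 276.3 MHz (7 comb teeth)
ring 1: correlation 1.0000, recovered RMS 7068 Pa
ring 2: correlation 0.9999, recovered RMS 7067 Pa
ring 3: correlation 0.9999, recovered RMS 7063 Pa
```

The tooth spacing, ring capacity and teeth-per-linewidth numbers are the
comb/array design arithmetic; the correlations say the demodulator
recovers each injected waveform essentially perfectly at the calibrated
receiver noise, and the recovered RMS (≈ 10 kPa/√2) confirms amplitude
fidelity. Imaging works the same way from recovered or simulated
waveforms:

```r
ph  <- make_phantom_microsphere()                 # 200 µm sphere, 4.8 mm/s
geo <- sensor_geometry(schedule = seq(0, 0.25, by = 0.05))
rec <- simulate_pressure(ph, geo, acoustic_medium(), sensor_response(),
                         fs_hz = 500e6, duration_s = 8e-6)
frames <- lapply(seq_along(geo$schedule), function(j) envelope_image(
  ubp_reconstruct(rec, geo, acoustic_medium(),
                  image_grid(c(-2e-3, 2e-3), c(3e-3, 7e-3), 25e-6),
                  step_subset = j)))
estimate_speed(frames, geo$schedule)$speed_m_per_s * 1e3   # ≈ 4.79 mm/s
```

A thin command-line front end (`inst/cli/dofcpat.R`, subcommands
`simulate / demodulate / reconstruct / characterize / capacity`) drives
the same functions from a YAML run configuration; see
`inst/extdata/default_run.yaml`.

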