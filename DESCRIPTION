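Package: dofcpat
Title: Frequency-Comb Parallel Interrogation of Micro-Ring Ultrasound
    Arrays and Photoacoustic Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator and signal-processing toolkit for parallel
    interrogation of a micro-ring resonator ultrasound sensor array with a
    digital optical frequency comb (DOFC), and for the downstream
    photoacoustic tomography (PAT) reconstruction.  Models the array's
    Lorentzian transmission spectrum and its pressure-induced resonance
    shifts, synthesizes the OFDM comb, simulates coherent detection with
    calibrated noise, demodulates frames into per-ring acoustic waveforms by
    resonance tracking, generates synthetic photoacoustic pressure records
    from phantoms with sensor bandwidth and acceptance-angle filtering, forms
    images by universal back-projection in rotational, static and linear-scan
    geometries, and reproduces the sensor characterization pipeline
    (impulse-response gating, bandwidth, acceptance-angle map,
    noise-equivalent pressure, closed-form resolution and capacity
    estimates).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    tiff,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
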