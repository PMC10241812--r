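# Parallel interrogation chain: null case, demodulation oracle, dip
# tracking, crosstalk, noise calibration, direct (CW) interrogation.

test_that("zero pressure and zero noise reproduce the null transmission spectrum", {
  arr <- small_array()
  w <- synthesize_comb(small_comb_spec())
  m <- interrogate(arr, matrix(0, 3, 32), w, noise_spec(sigma_rel = 0))
  sg <- demodulate_frames(m)
  null_tr <- transmission_spectrum(arr, sg$freq_offsets_hz)
  for (j in c(1, 16, 32)) {
    expect_equal(sg$transmission[, j], null_tr, tolerance = 1e-9)
  }
  # spectrogram bookkeeping: frame time axis spans n_frames x 25.6 ns analog
  expect_equal(diff(sg$times_s[1:2]), 1 / tooth_spacing(w$spec))
  expect_length(sg$times_s, 32)
})

test_that("demodulation recovers a synthetically applied Lorentzian exactly", {
  sp <- small_comb_spec()
  w <- synthesize_comb(sp)
  f <- sp$freqs_hz
  tr_true <- 1 - 0.8 * (150e6)^2 / ((f - 0.4e9)^2 + (150e6)^2)
  teeth_mod <- w$teeth * tr_true
  samples <- matrix(stats::fft(teeth_mod, inverse = TRUE) / sp$n_subcarriers)
  sg <- demodulate_frames(samples, spec = sp, reference = w$teeth)
  ord <- order(f[sp$occupied])
  expect_equal(sg$transmission[, 1], tr_true[sp$occupied][ord],
               tolerance = 1e-12)
})

test_that("demodulation demands a reference frame and whole frames", {
  sp <- small_comb_spec()
  w <- synthesize_comb(sp)
  m <- interrogate(small_array(), matrix(0, 3, 4), w)
  expect_error(demodulate_frames(m$samples, spec = sp), "reference")
  expect_error(demodulate_frames(as.vector(m$samples)[1:300], spec = sp,
                                 reference = w$teeth), "frames")
})

test_that("a single driven ring oscillates at its tone and the others stay quiet", {
  arr <- small_array()
  sp <- small_comb_spec()
  w <- synthesize_comb(sp)
  frate <- tooth_spacing(sp)
  nf <- 512
  t <- (0:(nf - 1)) / frate
  p <- matrix(0, 3, nf)
  p[2, ] <- 1e4 * sin(2 * pi * 1e6 * t)
  m <- interrogate(arr, p, w, noise_spec(sigma_rel = 0))
  fd <- fit_dips(demodulate_frames(m), arr)
  # driven ring recovers the tone
  expect_gt(stats::cor(fd$pressures_pa[, 2], p[2, ]), 0.9999)
  X <- Mod(stats::fft(fd$pressures_pa[, 2]))
  expect_equal(fft_freq_at_max <- abs(fft_freqs(nf, frate))[which.max(X[2:(nf / 2)]) + 1],
               1e6, tolerance = frate / nf / 1e6)
  # undriven rings stay at the noise-free floor
  expect_lt(max(abs(fd$pressures_pa[, c(1, 3)])), 0.02 * max(p[2, ]))
})

test_that("dip fitting is exact at zero noise for off-grid centers", {
  # dip centered exactly between two teeth
  sp <- small_comb_spec()
  w <- synthesize_comb(sp)
  shift <- tooth_spacing(sp) / 2
  arr <- ring_array(list(ring_resonance(0, 6e5, sensitivity_hz_per_pa = 1e4)),
                    spacing_hz = 1.66e9)
  p <- matrix(shift / 1e4, 1, 8)   # constant pressure placing dip between teeth
  m <- interrogate(arr, p, w, noise_spec(sigma_rel = 0))
  fd <- fit_dips(demodulate_frames(m), arr)
  expect_lt(max(abs(fd$shifts_hz - shift)), tooth_spacing(sp) / 100)
})

test_that("a step shift on one ring is recovered there and nowhere else", {
  arr <- small_array()
  w <- synthesize_comb(small_comb_spec())
  p <- matrix(0, 3, 16)
  p[3, ] <- 100e6 / 1e4            # +100 MHz via the 1e4 Hz/Pa sensitivity
  fd <- fit_dips(demodulate_frames(
    interrogate(arr, p, w, noise_spec(sigma_rel = 0))), arr)
  expect_equal(mean(fd$shifts_hz[, 3]), 100e6, tolerance = 1e-3)
  expect_lt(max(abs(fd$shifts_hz[, 1:2])), 1e6)
})

test_that("a dip drifting beyond its window raises a tracking error naming the ring", {
  arr <- small_array()
  w <- synthesize_comb(small_comb_spec())
  p <- matrix(0, 3, 16)
  p[1, ] <- (arr$spacing_hz * 0.75) / 1e4
  expect_error(fit_dips(demodulate_frames(
    interrogate(arr, p, w, noise_spec(sigma_rel = 0))), arr),
    "tracking error: ring 1")
})

test_that("demodulated shifts scale linearly with pressure amplitude", {
  arr <- small_array()
  w <- synthesize_comb(small_comb_spec())
  frate <- tooth_spacing(small_comb_spec())
  p1 <- tone_pressures(3, 256, frate, amp_pa = 5e3)
  p2 <- 2 * p1; attr(p2, "fs_hz") <- frate
  f1 <- fit_dips(demodulate_frames(
    interrogate(arr, p1, w, noise_spec(sigma_rel = 0))), arr)
  f2 <- fit_dips(demodulate_frames(
    interrogate(arr, p2, w, noise_spec(sigma_rel = 0))), arr)
  expect_equal(f2$shifts_hz, 2 * f1$shifts_hz, tolerance = 5e-3)
})

test_that("optional Levenberg-Marquardt refinement agrees with the closed form", {
  arr <- ring_array(list(ring_resonance(0, 6e5, sensitivity_hz_per_pa = 1e4)),
                    spacing_hz = 1.66e9)
  w <- synthesize_comb(small_comb_spec())
  p <- matrix(80e6 / 1e4, 1, 4)
  sg <- demodulate_frames(interrogate(arr, p, w, noise_spec(sigma_rel = 0)))
  plain <- fit_dips(sg, arr, refine = FALSE)
  ref <- fit_dips(sg, arr, refine = TRUE)
  expect_equal(ref$shifts_hz, plain$shifts_hz, tolerance = 1e-4)
})

test_that("aliasing above half the tooth spacing is flagged", {
  arr <- small_array()
  sp <- small_comb_spec()
  w <- synthesize_comb(sp)
  fs <- 500e6
  t <- (0:4095) / fs
  p <- rbind(1e3 * sin(2 * pi * 30e6 * t), 0 * t, 0 * t)  # 30 MHz > 19.5 MHz
  attr(p, "fs_hz") <- fs
  expect_warning(interrogate(arr, p, w), "detection limit")
  expect_error(interrogate(arr, p, w, on_alias = "error"), "detection limit")
})

test_that("noise-only runs hit the calibrated pressure noise floor", {
  arr <- default_ring_array()
  w <- synthesize_comb(comb_spec())
  ns <- noise_spec(seed = 202L)
  m <- interrogate(arr, matrix(0, 15, 384), w, ns, n_frames = 384)
  fd <- fit_dips(demodulate_frames(m), arr)
  floor_pa <- mean(apply(fd$pressures_pa, 2, function(z) sqrt(mean(z^2))))
  target <- ns$nep_target_pa *
    sqrt((tooth_spacing(w$spec) / 2) / ns$nep_band_hz)
  expect_equal(floor_pa, target, tolerance = 0.2)
  # sub-tooth tracking accuracy at the default noise level
  expect_lt(mean(apply(fd$shifts_hz, 2, stats::sd)),
            tooth_spacing(w$spec) / 10)
})

test_that("direct interrogation is linear in the small-signal regime", {
  ring <- ring_resonance(0, 6e5, sensitivity_hz_per_pa = 1e4)
  t <- (0:2047) / 500e6
  prec <- 50 * sin(2 * pi * 20e6 * t)     # 50 Pa: tiny shift vs 161 MHz hw
  out <- direct_interrogate(ring, prec, noise_spec(sigma_rel = 0))
  expect_gt(abs(stats::cor(out$output, prec)), 0.9999)
  # chain sensitivity converts output swing back to pressure
  swing <- (max(out$output) - min(out$output)) / 2
  expect_equal(swing / out$chain_sensitivity, 50, tolerance = 0.01)
})

test_that("the maximum-slope bias point is at FWHM/(2*sqrt(3)) off center", {
  ring <- ring_resonance(0, 6e5)
  hw <- fwhm_from_q(6e5) / 2
  offs <- seq(0.05, 3, by = 0.005) * hw
  slopes <- abs(vapply(offs, function(o) dip_slope(ring, o), numeric(1)))
  expect_equal(offs[which.max(slopes)] / hw, 1 / sqrt(3), tolerance = 0.01)
  # default bias uses that point
  out <- direct_interrogate(ring, numeric(16), noise_spec(sigma_rel = 0))
  expect_equal(out$bias_offset_hz, hw / sqrt(3))
  expect_error(direct_interrogate(ring, numeric(16), bias_offset_hz = 0),
               "zero slope")
})
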