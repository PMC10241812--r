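# Universal back-projection and image metrics.

med <- acoustic_medium()

test_that("all-zero waveforms reconstruct to an all-zero image", {
  geo <- sensor_geometry()
  rec <- structure(list(times_s = (0:999) / 500e6,
                        pressures_pa = array(0, c(1, 15, 1000)),
                        fs_hz = 500e6, t0_s = 0, geometry = geo,
                        medium = med, response = NULL,
                        phantom_name = "zero"),
                   class = "pressure_records")
  img <- ubp_reconstruct(rec, geo, med,
                         image_grid(c(-1e-3, 1e-3), c(0, 2e-3), 50e-6))
  expect_true(all(img$values == 0))
})

test_that("UBP is linear in the input waveforms", {
  geo <- sensor_geometry(positions = linear_sensor_array(8))
  pa <- point_phantom(-0.5e-3, 3e-3)
  pb <- point_phantom(0.7e-3, 4e-3)
  pab <- source_phantom(rbind(pa$elements, pb$elements), name = "both")
  g <- image_grid(c(-1.5e-3, 1.5e-3), c(2e-3, 5e-3), 50e-6)
  ia <- ubp_reconstruct(simulate_pressure(pa, geo, med, sensor_response(),
                                          500e6, 6e-6), geo, med, g)
  ib <- ubp_reconstruct(simulate_pressure(pb, geo, med, sensor_response(),
                                          500e6, 6e-6), geo, med, g)
  iab <- ubp_reconstruct(simulate_pressure(pab, geo, med, sensor_response(),
                                           500e6, 6e-6), geo, med, g)
  expect_equal(iab$values, ia$values + ib$values, tolerance = 1e-8)
})

test_that("full-view rotational UBP localizes an off-center point to sub-pixel error", {
  ph <- point_phantom(0.8e-3, 1.2e-3)
  geo <- sensor_geometry(mode = "rotational", schedule = seq(0, 354, by = 6))
  rec <- simulate_pressure(ph, geo, med, sensor_response(), 500e6, 8e-6)
  g <- image_grid(c(-2e-3, 2e-3), c(-2e-3, 2e-3), 25e-6)
  img <- ubp_reconstruct(rec, geo, med, g)
  pp <- peak_position(img, value = "signed")
  expect_lt(sqrt(sum((pp - c(0.8e-3, 1.2e-3))^2)), g$pixel_m)
})

test_that("empty apertures are rejected; sensor subsets work", {
  geo <- sensor_geometry(positions = linear_sensor_array(4))
  rec <- simulate_pressure(point_phantom(0, 3e-3), geo, med,
                           sensor_response(), 500e6, 5e-6)
  g <- image_grid(c(-1e-3, 1e-3), c(2e-3, 4e-3), 50e-6)
  expect_error(ubp_reconstruct(rec, geo, med, g, aperture = c(1, 2)),
               "empty aperture")
  i1 <- ubp_reconstruct(rec, geo, med, g, aperture = list(sensors = 2))
  expect_equal(i1$meta$n_detectors, 1L)
})

test_that("envelope is nonnegative, exact for a sinusoid line, and tightens profiles", {
  g <- image_grid(c(0, 2e-3), c(0, 2e-3), 20e-6)
  x <- seq_along(g$y)
  for (i in seq_along(g$x)) g$values[i, ] <- sin(2 * pi * x / 10)
  env <- envelope_image(g)
  expect_true(all(env$values >= 0))
  # interior samples of the envelope of a pure sinusoid equal its amplitude
  interior <- env$values[, 10:(length(g$y) - 10)]
  expect_equal(as.vector(interior), rep(1, length(interior)), tolerance = 0.05)
  # oscillatory point-target profile: envelope FWHM below zero-crossing width
  geo <- sensor_geometry(positions = linear_sensor_array(8))
  rec <- simulate_pressure(point_phantom(0, 3e-3), geo, med,
                           sensor_response(), 500e6, 5e-6)
  gi <- image_grid(c(-0.6e-3, 0.6e-3), c(2.6e-3, 3.4e-3), 5e-6)
  img <- ubp_reconstruct(rec, geo, med, gi)
  i0 <- which.min(abs(img$x))
  prof <- img$values[i0, ]
  wen <- profile_fwhm(img, list(axis = "y", at = 0), envelope = TRUE)
  wsigned <- profile_fwhm(img, list(axis = "y", at = 0), envelope = FALSE)
  # the envelope is the smooth upper bound of the oscillation: its FWHM
  # brackets the (narrower, center-frequency-set) single-lobe width and
  # stays on the axial-resolution scale of the sensor band
  expect_gte(wen, wsigned)
  expect_lt(wen, 60e-6)
})

test_that("CNR follows its definition and is scale invariant", {
  g <- image_grid(c(0, 1e-3), c(0, 1e-3), 20e-6)
  set.seed(5)
  g$values[] <- stats::rnorm(length(g$values), 0, 1)
  g$values[25, 25] <- 10
  sig <- list(xlim = c(0.4e-3, 0.56e-3), ylim = c(0.4e-3, 0.56e-3))
  bg <- list(xlim = c(0, 0.3e-3), ylim = c(0, 0.3e-3))
  v <- cnr(g, sig, bg)
  sd_bg <- stats::sd(as.vector(g$values[g$x >= 0 & g$x <= 0.3e-3,
                                        g$y >= 0 & g$y <= 0.3e-3]))
  expect_equal(v, 20 * log10(10 / sd_bg))
  g2 <- g; g2$values <- 7 * g$values
  expect_equal(cnr(g2, sig, bg), v)
  expect_error(cnr(g, sig, sig), "disjoint")
})

test_that("speed estimation: static targets give zero and subsampling is consistent", {
  # synthetic frames with a gaussian blob moving at constant speed
  mk <- function(cx, cy) {
    g <- image_grid(c(-2e-3, 2e-3), c(3e-3, 7e-3), 25e-6)
    X <- matrix(g$x, length(g$x), length(g$y))
    Y <- matrix(g$y, length(g$x), length(g$y), byrow = TRUE)
    g$values <- exp(-((X - cx)^2 + (Y - cy)^2) / (2 * (100e-6)^2))
    g
  }
  ts <- seq(0, 0.25, by = 0.05)
  frames <- lapply(ts, function(t) mk(0, 6e-3 - 4.8e-3 * t))
  est <- estimate_speed(frames, ts)
  expect_equal(est$speed_m_per_s, 4.8e-3, tolerance = 0.01)
  # subsampling the frame sequence leaves the estimate unchanged
  est2 <- estimate_speed(frames[c(1, 3, 5)], ts[c(1, 3, 5)])
  expect_equal(est2$speed_m_per_s, est$speed_m_per_s, tolerance = 0.01)
  static <- estimate_speed(frames[c(1, 1, 1)], ts[1:3])
  expect_lt(static$speed_m_per_s, 1e-9)
})

test_that("profile FWHM matches the Gaussian closed form and is scale invariant", {
  g <- image_grid(c(-1e-3, 1e-3), c(0, 1e-3), 10e-6)
  sgm <- 120e-6
  g$values <- matrix(exp(-g$x^2 / (2 * sgm^2)), length(g$x), length(g$y))
  w <- profile_fwhm(g, list(axis = "x", at = 0.5e-3), envelope = FALSE)
  expect_equal(w, 2 * sqrt(2 * log(2)) * sgm, tolerance = g$pixel_m / 2 / w)
  g2 <- g; g2$values <- 0.01 * g$values
  expect_equal(profile_fwhm(g2, list(axis = "x", at = 0.5e-3),
                            envelope = FALSE), w)
  # a profile that never falls below half max is an error
  gflat <- g; gflat$values[] <- 1
  expect_error(profile_fwhm(gflat, list(axis = "x", at = 0.5e-3)),
               "falls below")
})
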