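# Acoustic forward model: time of flight, spreading, superposition,
# angular response, phantoms, attenuation.

med <- acoustic_medium()

test_that("a point source arrives at the analytic time of flight", {
  src <- point_phantom(0, 5e-3)
  geo <- sensor_geometry(positions = matrix(c(0, 0), 1, 2))
  rec <- simulate_pressure(src, geo, med, sensor_response(), fs_hz = 500e6,
                           duration_s = 6e-6)
  x <- rec$pressures_pa[1, 1, ]
  t_peak <- rec$times_s[which.max(abs(x))]
  expect_equal(t_peak, 5e-3 / 1500, tolerance = 2 / 500e6 / (5e-3 / 1500))
})

test_that("equidistant sensors record identical waveforms", {
  src <- point_phantom(0, 4e-3)
  geo <- sensor_geometry(positions = rbind(c(-1e-3, 0), c(1e-3, 0)))
  rec <- simulate_pressure(src, geo, med, sensor_response(), fs_hz = 500e6,
                           duration_s = 6e-6)
  expect_equal(rec$pressures_pa[1, 1, ], rec$pressures_pa[1, 2, ],
               tolerance = 1e-10)
})

test_that("on-axis peak amplitude follows the 1/r law", {
  geo <- sensor_geometry(positions = matrix(c(0, 0), 1, 2))
  r1 <- simulate_pressure(point_phantom(0, 3e-3), geo, med, NULL,
                          fs_hz = 500e6, duration_s = 8e-6)
  r2 <- simulate_pressure(point_phantom(0, 6e-3), geo, med, NULL,
                          fs_hz = 500e6, duration_s = 8e-6)
  a1 <- max(abs(r1$pressures_pa[1, 1, ]))
  a2 <- max(abs(r2$pressures_pa[1, 1, ]))
  expect_equal(a1 / a2, 2, tolerance = 1e-3)
})

test_that("records superpose linearly over sources", {
  geo <- sensor_geometry(positions = matrix(c(0, 0), 1, 2))
  pa <- point_phantom(-1e-3, 4e-3)
  pb <- point_phantom(1.5e-3, 5.5e-3)
  pab <- source_phantom(rbind(pa$elements, pb$elements), name = "both")
  ra <- simulate_pressure(pa, geo, med, sensor_response(), 500e6, 7e-6)
  rb <- simulate_pressure(pb, geo, med, sensor_response(), 500e6, 7e-6)
  rab <- simulate_pressure(pab, geo, med, sensor_response(), 500e6, 7e-6)
  expect_equal(rab$pressures_pa[1, 1, ],
               ra$pressures_pa[1, 1, ] + rb$pressures_pa[1, 1, ],
               tolerance = 1e-9)
})

test_that("angular response is unity on axis, -3 dB at the acceptance angle, monotone", {
  resp <- sensor_response()
  expect_equal(angular_weight(resp, 0, 25e6), 1)
  expect_equal(angular_weight(resp, 0, 150e6), 1)
  expect_equal(angular_weight(resp, 30, 25e6), 10^(-3 / 20), tolerance = 1e-6)
  expect_equal(angular_weight(resp, -30, 25e6), 10^(-3 / 20), tolerance = 1e-6)
  sweep_w <- angular_weight(resp, seq(0, 89, by = 0.5), 25e6)
  expect_true(all(diff(sweep_w) <= 1e-12))
  expect_lt(angular_weight(resp, 45, 25e6), angular_weight(resp, 30, 25e6))
  # narrower acceptance at higher frequency
  expect_lt(angular_weight(resp, 30, 60e6), angular_weight(resp, 30, 25e6))
  expect_error(angular_weight(resp, 95, 25e6))
})

test_that("energy at a sensor decreases monotonically with source distance", {
  geo <- sensor_geometry(positions = matrix(c(0, 0), 1, 2))
  en <- vapply(c(2e-3, 3e-3, 4.5e-3, 6e-3), function(d) {
    r <- simulate_pressure(point_phantom(0, d), geo, med, sensor_response(),
                           500e6, 8e-6)
    sum(r$pressures_pa[1, 1, ]^2)
  }, numeric(1))
  expect_true(all(diff(en) < 0))
})

test_that("attenuation lowers the spectral centroid with distance", {
  medatt <- acoustic_medium(attenuation_db_per_cm_mhz = 1)
  geo <- sensor_geometry(positions = matrix(c(0, 0), 1, 2))
  centroid <- function(d) {
    r <- simulate_pressure(point_phantom(0, d), geo, medatt,
                           sensor_response(), 500e6, 10e-6)
    fr <- frequency_response(r$pressures_pa[1, 1, ], 500e6)
    sum(fr$freq_hz * fr$magnitude^2) / sum(fr$magnitude^2)
  }
  expect_lt(centroid(8e-3), centroid(2e-3))
})

test_that("figure-8 trajectory visits opposite lobes half a period apart", {
  ph <- make_phantom_figure8()
  p1 <- ph$trajectory(0.2 * 5e-3)
  p2 <- ph$trajectory(0.2 * 5e-3 + 2.5e-3)
  ctr <- c(0, 5e-3)
  # the Gerono lemniscate mirrors across the waist half a period later:
  # same lateral position, opposite lobe
  expect_equal(p1[1] - ctr[1], p2[1] - ctr[1], tolerance = 1e-12)
  expect_equal(p1[2] - ctr[2], -(p2[2] - ctr[2]), tolerance = 1e-12)
  expect_gt(abs(p1[2] - ctr[2]), 1e-4)
})

test_that("microsphere displacement equals speed times elapsed time", {
  ph <- make_phantom_microsphere()
  d <- ph$trajectory(1) - ph$trajectory(0)
  expect_equal(sqrt(sum(d^2)), 4.8e-3)
})

test_that("seeded phantoms are deterministic and leave the RNG untouched", {
  a <- make_phantom_leaf(seed = 3)
  set.seed(99); before <- stats::runif(1)
  b <- make_phantom_leaf(seed = 3)
  set.seed(99); after <- stats::runif(1)
  expect_identical(a$elements, b$elements)
  expect_identical(before, after)
  expect_false(identical(a$elements, make_phantom_leaf(seed = 4)$elements))
  h <- make_phantom_hairs()
  expect_gt(nrow(h$elements), 100)
})

test_that("moving phantoms track their trajectory across acquisition steps", {
  ph <- make_phantom_microsphere(start_m = c(0, 5e-3))
  geo <- sensor_geometry(positions = matrix(c(0, 0), 1, 2),
                         schedule = c(0, 0.5))
  rec <- simulate_pressure(ph, geo, med, sensor_response(), 500e6, 8e-6)
  t1 <- rec$times_s[which.max(abs(rec$pressures_pa[1, 1, ]))]
  t2 <- rec$times_s[which.max(abs(rec$pressures_pa[2, 1, ]))]
  # sphere moves 2.4 mm toward the sensor in 0.5 s
  expect_equal((t1 - t2) * 1500, 2.4e-3, tolerance = 0.02)
})
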