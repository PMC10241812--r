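# Acoustic forward model: phantoms, sensor frequency/angular response, and
# synthetic photoacoustic pressure records at the sensor positions.
#
# Coordinate convention: metres; sensor array along +x at y = 0 facing +y;
# sources in the y > 0 half plane; the imaging plane is z = 0 and spherical
# (1/r) spreading is retained. Angles counterclockwise positive.

#' Acoustic medium
#'
#' @param sound_speed_m_per_s Speed of sound (default 1500 m/s, water).
#' @param attenuation_db_per_cm_mhz Power-law attenuation coefficient
#'   (dB cm^-1 MHz^-exponent); default 0 (off).
#' @param attenuation_exponent Frequency power-law exponent (default 1).
#' @return An object of class \code{acoustic_medium}.
#' @export
acoustic_medium <- function(sound_speed_m_per_s = 1500,
                            attenuation_db_per_cm_mhz = 0,
                            attenuation_exponent = 1) {
  stopifnot(sound_speed_m_per_s > 0, attenuation_db_per_cm_mhz >= 0)
  structure(list(sound_speed_m_per_s = sound_speed_m_per_s,
                 attenuation_db_per_cm_mhz = attenuation_db_per_cm_mhz,
                 attenuation_exponent = attenuation_exponent),
            class = "acoustic_medium")
}

#' Sensor positions of a linear micro-ring array
#'
#' @param n_sensors Element count (default 15).
#' @param pitch_m Center-to-center distance (default 400 um).
#' @return n x 2 matrix of (x, y) positions, centered on the origin.
#' @export
linear_sensor_array <- function(n_sensors = 15, pitch_m = 400e-6) {
  x <- (seq_len(n_sensors) - (n_sensors + 1) / 2) * pitch_m
  cbind(x = x, y = rep(0, n_sensors))
}

#' Acquisition geometry
#'
#' Sensor coordinates plus the acquisition schedule. \code{rotational} mode
#' rotates the sample by \code{schedule} degrees about
#' \code{rotation_center_m} between steps (full-view tomography);
#' \code{linear_scan} translates the array along x by \code{schedule} metres;
#' \code{static} acquires frames at the \code{schedule} times (for moving
#' sources).
#'
#' @param positions n x 2 matrix of sensor (x, y) positions (default the
#'   15-element, 400-um-pitch line).
#' @param mode One of "static", "rotational", "linear_scan".
#' @param schedule Numeric acquisition schedule: angles (deg), x offsets (m)
#'   or frame times (s) according to mode. Default a single step at 0.
#' @param rotation_center_m Rotation center (rotational mode).
#' @return An object of class \code{sensor_geometry}.
#' @export
sensor_geometry <- function(positions = linear_sensor_array(),
                            mode = c("static", "rotational", "linear_scan"),
                            schedule = 0,
                            rotation_center_m = c(0, 0)) {
  mode <- match.arg(mode)
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2, nrow(positions) >= 1)
  if (anyDuplicated(positions)) stop("sensor positions must be distinct")
  if (length(schedule) < 1) stop("schedule must be nonempty")
  structure(list(positions = positions, mode = mode,
                 schedule = as.numeric(schedule),
                 rotation_center_m = rotation_center_m),
            class = "sensor_geometry")
}

#' Sensor frequency and angular response
#'
#' Band-pass magnitude response modeled as a Gaussian in frequency truncated
#' at DC, parameterized by the center frequency and the -6 dB bandwidth
#' (defaults 60 MHz and 175 MHz, the characterized values). The angular
#' response is a spatial-aperture (sinc) directivity whose effective element
#' width is calibrated so the gain is exactly -3 dB at the acceptance half
#' angle for the reference frequency (defaults: +/-30 degrees at 25 MHz).
#'
#' @param center_freq_hz Response center frequency f0 (Hz).
#' @param bw_6db_hz Contiguous -6 dB bandwidth (Hz).
#' @param bw_3db_hz Nominal -3 dB bandwidth (Hz), used by the closed-form
#'   axial-resolution estimate.
#' @param acceptance_half_angle_deg Half angle of the -3 dB acceptance cone.
#' @param acceptance_ref_freq_hz Frequency at which the acceptance angle is
#'   defined (Hz).
#' @param sound_speed_m_per_s Sound speed used to calibrate the aperture.
#' @return An object of class \code{sensor_response}.
#' @export
sensor_response <- function(center_freq_hz = 60e6, bw_6db_hz = 175e6,
                            bw_3db_hz = 115e6,
                            acceptance_half_angle_deg = 30,
                            acceptance_ref_freq_hz = 25e6,
                            sound_speed_m_per_s = 1500) {
  stopifnot(center_freq_hz > 0, bw_6db_hz > 0, bw_3db_hz <= bw_6db_hz,
            acceptance_half_angle_deg > 0, acceptance_half_angle_deg < 90)
  # Gaussian sigma from the -6 dB band: the band is [max(0, f0-x), f0+x]
  # with exp(-x^2 / (2 sigma^2)) = 0.5; when it truncates at DC the upper
  # edge alone sets the width.
  xhalf <- sqrt(2 * log(2))
  sigma_untrunc <- bw_6db_hz / 2 / xhalf
  sigma_f <- if (center_freq_hz - bw_6db_hz / 2 < 0) {
    (bw_6db_hz - center_freq_hz) / xhalf
  } else {
    sigma_untrunc
  }
  # sinc argument x0 with sin(x0)/x0 = 10^(-3/20); aperture a from
  # x0 = pi a f sin(theta) / v at the reference point.
  target <- 10^(-3 / 20)
  x0 <- stats::uniroot(function(x) sin(x) / x - target, c(1e-6, pi - 1e-6),
                       tol = 1e-12)$root
  aperture_m <- x0 * sound_speed_m_per_s /
    (pi * acceptance_ref_freq_hz * sin(acceptance_half_angle_deg * pi / 180))
  structure(list(center_freq_hz = center_freq_hz, bw_6db_hz = bw_6db_hz,
                 bw_3db_hz = bw_3db_hz,
                 acceptance_half_angle_deg = acceptance_half_angle_deg,
                 acceptance_ref_freq_hz = acceptance_ref_freq_hz,
                 sigma_f_hz = sigma_f, aperture_m = aperture_m,
                 sound_speed_m_per_s = sound_speed_m_per_s),
            class = "sensor_response")
}

#' Sensor magnitude response at given frequencies
#'
#' @param response A \code{sensor_response}.
#' @param freq_hz Frequencies (Hz, may be signed; the response is even).
#' @return Magnitude gain, peak-normalized to 1 at \code{center_freq_hz}.
#' @export
response_spectrum <- function(response, freq_hz) {
  exp(-(abs(freq_hz) - response$center_freq_hz)^2 /
        (2 * response$sigma_f_hz^2))
}

#' Unit-energy impulse kernel of the sensor
#'
#' Zero-phase band-pass kernel obtained by inverse transform of the
#' magnitude response, centered in a window of \code{n} samples.
#'
#' @param response A \code{sensor_response}.
#' @param fs_hz Sampling rate (Hz).
#' @param n Kernel length in samples (even recommended).
#' @return Numeric kernel with unit energy.
#' @export
impulse_kernel <- function(response, fs_hz, n = 256) {
  M <- response_spectrum(response, fft_freqs(n, fs_hz))
  k <- Re(stats::fft(M, inverse = TRUE) / n)
  k <- c(k[(n / 2 + 1):n], k[1:(n / 2)])  # center the peak
  k / sqrt(sum(k^2))
}

#' Angular sensitivity of the sensor
#'
#' Spatial-aperture directivity \eqn{\mathrm{sinc}(\pi a f \sin|\theta| / v)},
#' clipped to zero beyond its first null so the gain is monotone
#' non-increasing in |angle|. Gain is 1 on axis and -3 dB at the acceptance
#' half angle for the reference frequency.
#'
#' @param response A \code{sensor_response}.
#' @param angle_deg Incidence angle(s) from the sensor normal (degrees,
#'   |angle| < 90).
#' @param freq_hz Acoustic frequency (Hz), scalar or same length as angle.
#' @param sound_speed_m_per_s Sound speed (m/s).
#' @return Dimensionless gain in [0, 1].
#' @export
angular_weight <- function(response, angle_deg, freq_hz,
                           sound_speed_m_per_s = response$sound_speed_m_per_s) {
  if (any(abs(angle_deg) >= 90)) stop("|angle_deg| must be < 90")
  x <- pi * response$aperture_m * abs(freq_hz) *
    sin(abs(angle_deg) * pi / 180) / sound_speed_m_per_s
  w <- ifelse(x < 1e-12, 1, sin(pmin(x, pi)) / pmax(x, 1e-12))
  pmax(w, 0)
}

# ---------------------------------------------------------------------------
# Phantoms

#' Source phantom
#'
#' A set of photoacoustic absorbers. Each element is a point (or
#' finite-radius sphere) at (x, y) with amplitude in Pa.m (pressure at 1 m
#' before filtering). The temporal signature is one of:
#' \itemize{
#'   \item \code{"delta"}: impulse (the sensor kernel shapes the record);
#'   \item \code{"gaussian_derivative"}: bipolar pulse from a Gaussian
#'     heating pulse of FWHM \code{pulse_fwhm_s};
#'   \item \code{"n_shape"}: the bipolar N-wave of a uniformly absorbing
#'     sphere of the element radius.
#' }
#' An optional \code{trajectory(t)} returning (x, y) makes the whole phantom
#' translate for moving-source acquisitions.
#'
#' @param elements data.frame with columns x, y, radius, amplitude.
#' @param signature Temporal signature (see above); the bipolar
#'   \code{"gaussian_derivative"} default is the proper photoacoustic pulse
#'   for imaging, while \code{"delta"} is meant for impulse-response
#'   characterization of the sensor itself.
#' @param pulse_fwhm_s Gaussian excitation FWHM (s), default 6.5 ns.
#' @param trajectory Optional function(t) -> c(x, y) displacement of the
#'   phantom origin at time t.
#' @param name Phantom name.
#' @return An object of class \code{source_phantom}.
#' @export
source_phantom <- function(elements,
                           signature = c("gaussian_derivative", "delta",
                                         "n_shape"),
                           pulse_fwhm_s = 6.5e-9, trajectory = NULL,
                           name = "phantom") {
  signature <- match.arg(signature)
  elements <- as.data.frame(elements)
  need <- c("x", "y", "radius", "amplitude")
  if (!all(need %in% names(elements))) {
    stop("elements needs columns: ", paste(need, collapse = ", "))
  }
  if (any(elements$radius < 0)) stop("radii must be >= 0")
  structure(list(elements = elements, signature = signature,
                 pulse_fwhm_s = pulse_fwhm_s, trajectory = trajectory,
                 name = name),
            class = "source_phantom")
}

#' @export
print.source_phantom <- function(x, ...) {
  cat(sprintf("<source_phantom> '%s': %d elements, %s signature%s\n",
              x$name, nrow(x$elements), x$signature,
              if (!is.null(x$trajectory)) ", moving" else ""))
  invisible(x)
}

#' Figure-8 hot-spot phantom
#'
#' A point absorber travelling a lemniscate ('8'-shaped) trajectory,
#' emulating a laser focus scanned on an absorbing tape.
#'
#' @param half_width_m,half_height_m Lobe extents (m).
#' @param period_s Trajectory period (s).
#' @param center_m Center of the figure (m).
#' @param amplitude Source amplitude (Pa.m).
#' @return A moving \code{source_phantom}.
#' @export
make_phantom_figure8 <- function(half_width_m = 1.5e-3, half_height_m = 2.5e-3,
                                 period_s = 5e-3, center_m = c(0, 5e-3),
                                 amplitude = 1) {
  traj <- function(t) {
    th <- 2 * pi * t / period_s
    c(center_m[1] + half_width_m * sin(th) * cos(th),
      center_m[2] + half_height_m * sin(th))
  }
  source_phantom(data.frame(x = 0, y = 0, radius = 0, amplitude = amplitude),
                 trajectory = traj, name = "figure8")
}

#' Moving microsphere phantom
#'
#' A 200-um polystyrene sphere pulled through a tube at constant speed
#' (default 4.8 mm/s, downward).
#'
#' @param speed_m_per_s Constant speed (m/s).
#' @param direction Unit-normalized direction of motion.
#' @param start_m Position at t = 0 (m).
#' @param diameter_m Sphere diameter (m).
#' @param amplitude Source amplitude (Pa.m).
#' @return A moving \code{source_phantom}.
#' @export
make_phantom_microsphere <- function(speed_m_per_s = 4.8e-3,
                                     direction = c(0, -1),
                                     start_m = c(0, 6e-3),
                                     diameter_m = 200e-6, amplitude = 1) {
  dirn <- direction / sqrt(sum(direction^2))
  traj <- function(t) start_m + dirn * speed_m_per_s * t
  source_phantom(
    data.frame(x = 0, y = 0, radius = diameter_m / 2, amplitude = amplitude),
    signature = "n_shape", trajectory = traj, name = "microsphere")
}

# Rasterize line segments (n x 4 matrix x0,y0,x1,y1) to point elements.
rasterize_segments <- function(segments, spacing_m = 25e-6, amplitude = 1) {
  pts <- do.call(rbind, lapply(seq_len(nrow(segments)), function(i) {
    s <- segments[i, ]
    len <- sqrt((s[3] - s[1])^2 + (s[4] - s[2])^2)
    n <- max(2L, ceiling(len / spacing_m) + 1L)
    u <- seq(0, 1, length.out = n)
    cbind(s[1] + u * (s[3] - s[1]), s[2] + u * (s[4] - s[2]))
  }))
  data.frame(x = pts[, 1], y = pts[, 2], radius = 0,
             amplitude = amplitude)
}

#' Crossed-hair phantom
#'
#' Three interleaved straight absorbing hairs at distinct crossing angles,
#' rasterized to point sources.
#'
#' @param length_m Hair length (m).
#' @param angles_deg Orientation of each hair (degrees).
#' @param center_m Crossing region center (m).
#' @param spacing_m Rasterization spacing (m).
#' @param amplitude Source amplitude per point (Pa.m).
#' @return A \code{source_phantom}.
#' @export
make_phantom_hairs <- function(length_m = 6e-3,
                               angles_deg = c(15, 80, 135),
                               center_m = c(0, 6e-3),
                               spacing_m = 50e-6, amplitude = 1) {
  # offset each hair slightly so they interleave rather than meet at a point
  offs <- list(c(0, -0.4e-3), c(0.3e-3, 0.2e-3), c(-0.3e-3, 0.3e-3))
  segs <- t(vapply(seq_along(angles_deg), function(i) {
    th <- angles_deg[i] * pi / 180
    d <- c(cos(th), sin(th)) * length_m / 2
    c0 <- center_m + offs[[(i - 1) %% 3 + 1]]
    c(c0 - d, c0 + d)
  }, numeric(4)))
  source_phantom(rasterize_segments(segs, spacing_m, amplitude),
                 name = "hairs")
}

#' Leaf-vein skeleton phantom
#'
#' Seeded recursive branching polyline skeleton emulating leaf veins,
#' rasterized to point sources. Deterministic per seed.
#'
#' @param seed RNG seed for the branching geometry.
#' @param extent_m Overall skeleton extent (m).
#' @param depth Branching depth.
#' @param center_m Skeleton center (m).
#' @param spacing_m Rasterization spacing (m).
#' @param amplitude Source amplitude per point (Pa.m).
#' @return A \code{source_phantom}.
#' @export
make_phantom_leaf <- function(seed = 1L, extent_m = 6e-3, depth = 3,
                              center_m = c(0, 6e-3), spacing_m = 50e-6,
                              amplitude = 1) {
  segs <- with_seed(seed, {
    grow <- function(p, angle, len, d) {
      q <- p + c(cos(angle), sin(angle)) * len
      seg <- matrix(c(p, q), 1, 4)
      if (d == 0) return(seg)
      kids <- lapply(c(-1, 1), function(s) {
        grow(p + (q - p) * stats::runif(1, 0.3, 0.7),
             angle + s * stats::runif(1, 0.5, 1.1),
             len * stats::runif(1, 0.4, 0.6), d - 1)
      })
      do.call(rbind, c(list(seg), kids))
    }
    grow(center_m - c(0, extent_m / 2), pi / 2, extent_m, depth)
  })
  source_phantom(rasterize_segments(segs, spacing_m, amplitude),
                 name = "leaf")
}

# ---------------------------------------------------------------------------
# Forward simulation

# Base source pulse, unit peak amplitude, centered at t = 0 within the
# length-n circular window.
source_pulse <- function(phantom, n, fs_hz, sound_speed, radius) {
  t <- (0:(n - 1)) / fs_hz
  t[t > (n / 2) / fs_hz] <- t[t > (n / 2) / fs_hz] - n / fs_hz
  if (phantom$signature == "delta" && radius == 0) {
    p <- numeric(n); p[1] <- 1
  } else if (phantom$signature == "n_shape" || radius > 0) {
    tau <- max(radius, 1e-9) / sound_speed
    p <- ifelse(abs(t) < tau, -t / tau, 0)
  } else {  # gaussian derivative
    sg <- phantom$pulse_fwhm_s / (2 * sqrt(2 * log(2)))
    p <- -t / sg * exp(0.5 - t^2 / (2 * sg^2))
  }
  p
}

#' Simulate photoacoustic pressure records
#'
#' Generates the per-sensor pressure time series for a phantom: each element
#' contributes its temporal signature delayed by the time of flight, scaled
#' by 1/r, filtered by the sensor band-pass response, weighted by the angular
#' response at its incidence angle, with optional power-law attenuation.
#' Superposition over elements; all filtering is applied in the frequency
#' domain (exact fractional delays).
#'
#' @param phantom A \code{source_phantom}.
#' @param geometry A \code{sensor_geometry}.
#' @param medium An \code{acoustic_medium}.
#' @param response A \code{sensor_response}, or NULL for an ideal (flat,
#'   isotropic) sensor.
#' @param fs_hz Sampling rate (default 500 MS/s).
#' @param duration_s Record length (s); default covers the maximum time of
#'   flight plus 1 us.
#' @param t0_s Acquisition start time relative to excitation (default 0).
#' @return An object of class \code{pressure_records}: list with
#'   \code{times_s}, \code{pressures_pa} (array steps x sensors x samples),
#'   \code{fs_hz}, \code{geometry}, \code{medium}, \code{response}.
#' @export
simulate_pressure <- function(phantom, geometry, medium = acoustic_medium(),
                              response = sensor_response(), fs_hz = 500e6,
                              duration_s = NULL, t0_s = 0) {
  stopifnot(inherits(phantom, "source_phantom"),
            inherits(geometry, "sensor_geometry"))
  v <- medium$sound_speed_m_per_s
  if (!is.null(response) && fs_hz < 2 * (response$center_freq_hz +
                                         1.5 * response$sigma_f_hz)) {
    warning("fs_hz below twice the sensor band edge; response will alias")
  }
  steps <- geometry$schedule
  nstep <- length(steps)
  nsens <- nrow(geometry$positions)

  elem0 <- phantom$elements
  if (is.null(duration_s)) {
    # conservative: max distance over schedule at step positions
    dmax <- 0
    for (j in seq_len(nstep)) {
      el <- step_elements(phantom, geometry, j)
      pos <- step_positions(geometry, j)
      for (s in seq_len(nrow(pos))) {
        dmax <- max(dmax, sqrt((el$x - pos[s, 1])^2 + (el$y - pos[s, 2])^2))
      }
    }
    duration_s <- dmax / v + 1e-6 - t0_s
  }
  n <- as.integer(round(duration_s * fs_hz))
  stopifnot(n >= 8)
  f <- fft_freqs(n, fs_hz)
  Mf <- if (is.null(response)) rep(1, n) else response_spectrum(response, f)
  out <- array(0, dim = c(nstep, nsens, n))
  pulse_cache <- new.env(parent = emptyenv())

  for (j in seq_len(nstep)) {
    el <- step_elements(phantom, geometry, j)
    pos <- step_positions(geometry, j)
    if (nrow(el) == 0) next
    for (s in seq_len(nsens)) {
      acc <- complex(n)
      for (e in seq_len(nrow(el))) {
        dx <- el$x[e] - pos[s, 1]; dy <- el$y[e] - pos[s, 2]
        r <- sqrt(dx^2 + dy^2)
        if (r < 1e-6) {
          warning("source within 1 um of a sensor; skipped")
          next
        }
        delay <- r / v - t0_s
        if (delay > duration_s) {
          warning("source outside the causal window; contribution truncated")
          next
        }
        ang <- atan2(abs(dx), dy) * 180 / pi  # from sensor normal (+y)
        wang <- if (is.null(response)) 1 else {
          if (ang >= 90) 0 else angular_weight(response, ang, f, v)
        }
        key <- sprintf("%.6g", el$radius[e])
        if (is.null(pulse_cache[[key]])) {
          pulse_cache[[key]] <-
            stats::fft(source_pulse(phantom, n, fs_hz, v, el$radius[e]))
        }
        S <- pulse_cache[[key]]
        att <- if (medium$attenuation_db_per_cm_mhz > 0) {
          10^(-medium$attenuation_db_per_cm_mhz *
                (abs(f) / 1e6)^medium$attenuation_exponent * (r * 100) / 20)
        } else 1
        acc <- acc + S * Mf * wang * att *
          exp(-2i * pi * f * delay) * (el$amplitude[e] / r)
      }
      out[j, s, ] <- Re(stats::fft(acc, inverse = TRUE) / n)
    }
  }
  structure(list(times_s = t0_s + (0:(n - 1)) / fs_hz, pressures_pa = out,
                 fs_hz = fs_hz, t0_s = t0_s, geometry = geometry,
                 medium = medium, response = response,
                 phantom_name = phantom$name),
            class = "pressure_records")
}

# Element coordinates at acquisition step j (applies trajectory and sample
# rotation).
step_elements <- function(phantom, geometry, j) {
  el <- phantom$elements
  if (!is.null(phantom$trajectory)) {
    tj <- if (geometry$mode == "static") geometry$schedule[j] else 0
    p <- phantom$trajectory(tj)
    el$x <- el$x + p[1]; el$y <- el$y + p[2]
  }
  if (geometry$mode == "rotational") {
    xy <- rotate_points(cbind(el$x, el$y), geometry$schedule[j],
                        geometry$rotation_center_m)
    el$x <- xy[, 1]; el$y <- xy[, 2]
  }
  el
}

# Sensor positions at acquisition step j (applies linear scan offset).
step_positions <- function(geometry, j) {
  pos <- geometry$positions
  if (geometry$mode == "linear_scan") {
    pos[, 1] <- pos[, 1] + geometry$schedule[j]
  }
  pos
}

#' @export
print.pressure_records <- function(x, ...) {
  d <- dim(x$pressures_pa)
  cat(sprintf(
    "<pressure_records> '%s': %d step(s) x %d sensor(s) x %d samples @ %.0f MS/s\n",
    x$phantom_name, d[1], d[2], d[3], x$fs_hz / 1e6))
  invisible(x)
}

#' Export pressure records as per-sensor CSV
#'
#' One CSV per acquisition step: a time column plus one column per sensor.
#' @param records A \code{pressure_records}.
#' @param path Output path; for multi-step records a step suffix is added.
#' @return Paths written, invisibly.
#' @export
export_pressure_csv <- function(records, path) {
  d <- dim(records$pressures_pa)
  paths <- character(d[1])
  for (j in seq_len(d[1])) {
    p <- if (d[1] == 1) path else
      sub("(\\.[^.]+)?$", sprintf("_step%03d\\1", j), path)
    m <- t(records$pressures_pa[j, , , drop = TRUE])
    if (d[2] == 1) m <- matrix(records$pressures_pa[j, 1, ], ncol = 1)
    df <- data.frame(time_s = records$times_s, m)
    names(df) <- c("time_s", paste0("sensor_", seq_len(d[2])))
    utils::write.csv(df, p, row.names = FALSE)
    paths[j] <- p
  }
  invisible(paths)
}
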