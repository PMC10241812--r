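# Sensor characterization pipeline: impulse-response gating, frequency
# response and bandwidth, acceptance-angle map, noise-equivalent pressure,
# and the closed-form resolution predictions.

#' Time-gate a record
#'
#' Zeroes samples outside a time window, with an optional raised-cosine
#' taper at each edge; used to keep only the first-arriving signal and
#' reject substrate reflections.
#'
#' @param x Pressure series.
#' @param fs_hz Sampling rate (Hz).
#' @param window_s Length-2 gate (s), relative to \code{t0_s}.
#' @param taper_s Raised-cosine edge length (s); 0 gives a hard gate.
#' @param t0_s Time of the first sample (default 0).
#' @return Gated series, same length.
#' @export
time_gate <- function(x, fs_hz, window_s, taper_s = 0, t0_s = 0) {
  stopifnot(length(window_s) == 2, window_s[2] > window_s[1])
  t <- t0_s + (seq_along(x) - 1) / fs_hz
  if (window_s[1] > max(t) || window_s[2] < min(t)) {
    stop("gate window lies outside the record span")
  }
  g <- as.numeric(t >= window_s[1] & t <= window_s[2])
  if (taper_s > 0) {
    ramp <- function(d) 0.5 * (1 - cos(pi * pmin(pmax(d / taper_s, 0), 1)))
    g <- g * ramp(t - window_s[1]) * ramp(window_s[2] - t)
  }
  x * g
}

#' Magnitude frequency response of a gated record
#'
#' Peak-normalized magnitude spectrum of the (time-gated) impulse response,
#' zero-padded for interpolation.
#'
#' @param gated Gated pressure series (nonzero).
#' @param fs_hz Sampling rate (Hz).
#' @param pad Zero-padding factor (default 4).
#' @return List with \code{freq_hz} (0..Nyquist) and \code{magnitude}
#'   (peak-normalized), of class \code{freq_response}.
#' @export
frequency_response <- function(gated, fs_hz, pad = 4) {
  if (all(gated == 0)) stop("gated series is identically zero")
  n <- length(gated)
  nfft <- 2^ceiling(log2(n * pad))
  X <- Mod(stats::fft(c(gated, numeric(nfft - n))))
  half <- 1:(nfft %/% 2 + 1)
  mag <- X[half] / max(X[half])
  structure(list(freq_hz = (half - 1) * fs_hz / nfft, magnitude = mag),
            class = "freq_response")
}

#' Bandwidth of a spectrum at a dB level
#'
#' Width of the contiguous band around the global peak where the magnitude
#' stays at or above \code{10^(level_db/20)}, with linearly interpolated
#' edges; secondary lobes are ignored. Also reports the band edges and the
#' spectral centroid over the band (the center-frequency estimate).
#'
#' @param spectrum A \code{freq_response} (or list with \code{freq_hz},
#'   \code{magnitude}).
#' @param level_db Level below peak, negative (e.g. -6).
#' @return List: \code{bandwidth_hz}, \code{lo_hz}, \code{hi_hz},
#'   \code{center_hz}.
#' @export
bandwidth_at_db <- function(spectrum, level_db) {
  if (level_db >= 0) stop("level_db must be negative")
  f <- spectrum$freq_hz; m <- spectrum$magnitude
  thr <- 10^(level_db / 20)
  i0 <- which.max(m)
  lo <- f[1]
  if (i0 > 1) for (i in i0:2) {
    if (m[i - 1] < thr) {
      lo <- f[i - 1] + (thr - m[i - 1]) / (m[i] - m[i - 1]) * (f[i] - f[i - 1])
      break
    }
  }
  hi <- f[length(f)]
  if (i0 < length(m)) for (i in i0:(length(m) - 1)) {
    if (m[i + 1] < thr) {
      hi <- f[i] + (m[i] - thr) / (m[i] - m[i + 1]) * (f[i + 1] - f[i])
      break
    }
  }
  inband <- f >= lo & f <= hi
  list(bandwidth_hz = hi - lo, lo_hz = lo, hi_hz = hi,
       center_hz = sum(f[inband] * m[inband]) / sum(m[inband]))
}

#' Frequency-vs-acceptance-angle map
#'
#' Converts a linear sensor sweep past a fixed point source into the angular
#' frequency response: per sweep offset, the incidence angle follows from
#' the lateral offset and standoff; per angle, the gated record's magnitude
#' spectrum is taken, compensated for spherical spreading (the known 1/r),
#' and normalized per frequency to its maximum over angle.
#'
#' @param records A \code{pressure_records} from a \code{linear_scan} sweep
#'   of a single sensor (or a single-step multi-sensor line).
#' @param source_position Source (x, y) in metres.
#' @param gate_s Optional gate length (s) around each first arrival;
#'   default +/- 0.4 us.
#' @return List of class \code{angle_map}: \code{freq_hz},
#'   \code{angle_deg}, \code{magnitude} (freq x angle, each row normalized
#'   to max 1).
#' @export
angle_map <- function(records, source_position, gate_s = 0.8e-6) {
  stopifnot(inherits(records, "pressure_records"))
  d <- dim(records$pressures_pa)
  geometry <- records$geometry
  v <- records$medium$sound_speed_m_per_s
  # flatten (steps, sensors) into a list of detector positions + series
  dets <- list()
  for (j in seq_len(d[1])) {
    pos <- step_positions(geometry, j)
    for (s in seq_len(d[2])) {
      dets[[length(dets) + 1]] <-
        list(pos = pos[s, ], x = records$pressures_pa[j, s, ])
    }
  }
  if (abs(source_position[2]) < 1e-9) stop("source standoff is zero")
  n <- length(dets)
  ang <- numeric(n)
  mags <- NULL
  ns <- length(dets[[1]]$x)
  nfft <- 2^ceiling(log2(ns * 2))
  half <- 1:(nfft %/% 2 + 1)
  freq <- (half - 1) * records$fs_hz / nfft
  for (k in seq_len(n)) {
    p <- dets[[k]]
    dx <- source_position[1] - p$pos[1]
    dy <- source_position[2] - p$pos[2]
    r <- sqrt(dx^2 + dy^2)
    ang[k] <- atan2(dx, dy) * 180 / pi
    tof <- r / v
    g <- time_gate(p$x, records$fs_hz,
                   c(tof - gate_s / 2, tof + gate_s / 2),
                   t0_s = records$times_s[1])
    X <- Mod(stats::fft(c(g, numeric(nfft - ns))))[half]
    if (is.null(mags)) mags <- matrix(0, length(half), n)
    # undo spherical spreading so the map reflects the sensor alone
    mags[, k] <- X * r
  }
  ord <- order(ang)
  mags <- mags[, ord, drop = FALSE]
  mx <- apply(mags, 1, max)
  mags <- mags / pmax(mx, 1e-300)
  structure(list(freq_hz = freq, angle_deg = ang[ord], magnitude = mags),
            class = "angle_map")
}

#' Acceptance-angle contour of an angle map
#'
#' Interpolates, at a given frequency, the angles on each side of the axis
#' where the normalized response crosses a dB level (default -3 dB).
#'
#' @param map An \code{angle_map}.
#' @param freq_hz Frequency at which to extract the contour (Hz).
#' @param level_db Contour level (dB below the per-frequency maximum).
#' @return Named vector \code{c(neg = , pos = )} of crossing angles (deg),
#'   NA where the response never falls below the level on that side.
#' @export
acceptance_contour <- function(map, freq_hz, level_db = -3) {
  thr <- 10^(level_db / 20)
  i <- which.min(abs(map$freq_hz - freq_hz))
  resp <- map$magnitude[i, ]
  a <- map$angle_deg
  i0 <- which.max(resp)
  neg <- NA_real_
  if (i0 > 1) for (k in i0:2) {
    if (resp[k - 1] < thr) {
      neg <- a[k] + (resp[k] - thr) / (resp[k] - resp[k - 1]) * (a[k - 1] - a[k])
      break
    }
  }
  pos <- NA_real_
  if (i0 < length(a)) for (k in i0:(length(a) - 1)) {
    if (resp[k + 1] < thr) {
      pos <- a[k] + (resp[k] - thr) / (resp[k] - resp[k + 1]) * (a[k + 1] - a[k])
      break
    }
  }
  c(neg = neg, pos = pos)
}

#' Welch amplitude spectral density
#'
#' Hann-windowed, overlapped segment averaging; returns the one-sided
#' amplitude spectral density in input units per sqrt(Hz), so white noise of
#' per-sample standard deviation \code{s} at rate \code{fs} has density
#' \code{s * sqrt(2 / fs)} and integrates to \code{s} over the full Nyquist
#' band.
#'
#' @param x Real series.
#' @param fs_hz Sampling rate (Hz).
#' @param segment Segment length (samples); default gives ~8 segments.
#' @param overlap Fractional overlap (default 0.5).
#' @return List: \code{freq_hz}, \code{asd} (units/sqrt(Hz)).
#' @export
welch_asd <- function(x, fs_hz, segment = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(segment)) segment <- max(16L, 2^floor(log2(n / 4.5)))
  segment <- min(segment, n)
  w <- 0.5 * (1 - cos(2 * pi * (0:(segment - 1)) / (segment - 1)))  # Hann
  step <- max(1L, floor(segment * (1 - overlap)))
  starts <- seq(1L, n - segment + 1L, by = step)
  acc <- numeric(segment %/% 2 + 1)
  for (s0 in starts) {
    seg <- x[s0:(s0 + segment - 1)] * w
    X <- Mod(stats::fft(seg))^2
    acc <- acc + X[1:(segment %/% 2 + 1)]
  }
  U <- sum(w^2)
  psd <- acc / length(starts) / (fs_hz * U)        # two-sided
  psd[2:(length(psd) - 1)] <- 2 * psd[2:(length(psd) - 1)]  # one-sided
  list(freq_hz = (0:(segment %/% 2)) * fs_hz / segment, asd = sqrt(psd))
}

#' Noise-equivalent pressure
#'
#' Welch amplitude spectral density of a noise-only detector record divided
#' by the end-to-end sensitivity (output units per Pa), giving the NEP
#' spectral density in Pa/sqrt(Hz); the integrated NEP over a band is the
#' square root of the band integral of the squared density.
#'
#' @param noise_record Noise-only detector output series.
#' @param sensitivity_chain End-to-end sensitivity (output units per Pa);
#'   1 if the record is already pressure-referred.
#' @param band_hz Length-2 integration band (Hz), within Nyquist.
#' @param fs_hz Sampling rate (Hz).
#' @param segment Welch segment length (see \code{\link{welch_asd}}).
#' @return List: \code{freq_hz}, \code{density_pa_per_sqrt_hz},
#'   \code{integrated_pa}, \code{band_hz}.
#' @export
nep <- function(noise_record, sensitivity_chain = 1, band_hz, fs_hz,
                segment = NULL) {
  stopifnot(length(band_hz) == 2, band_hz[1] >= 0)
  if (band_hz[2] > fs_hz / 2 * (1 + 1e-9)) {
    stop("band exceeds the Nyquist frequency ", fs_hz / 2, " Hz")
  }
  w <- welch_asd(noise_record, fs_hz, segment)
  dens <- w$asd / sensitivity_chain
  sel <- w$freq_hz >= band_hz[1] & w$freq_hz <= band_hz[2]
  df <- w$freq_hz[2] - w$freq_hz[1]
  integrated <- sqrt(sum(dens[sel]^2) * df)
  list(freq_hz = w$freq_hz, density_pa_per_sqrt_hz = dens,
       integrated_pa = integrated, band_hz = band_hz)
}

#' Closed-form resolution estimates
#'
#' Partial-view PAT resolution formulas: lateral
#' \eqn{0.71\, v / (\mathrm{NA}\, f_0)} and axial \eqn{0.88\, v / \Delta f},
#' with NA the numerical aperture from the acceptance half angle, f0 the
#' center frequency and \eqn{\Delta f} the -3 dB bandwidth. At the default
#' sensor parameters (v = 1500 m/s, NA = 0.5, f0 = 60 MHz,
#' \eqn{\Delta f} = 115 MHz): 35.5 um lateral, 11.5 um axial.
#'
#' @param sound_speed_m_per_s Speed of sound (m/s).
#' @param numerical_aperture NA = sin(acceptance half angle), in (0, 1].
#' @param center_freq_hz Sensor center frequency f0 (Hz).
#' @return Resolution in metres.
#' @export
lateral_resolution <- function(sound_speed_m_per_s = 1500,
                               numerical_aperture = 0.5,
                               center_freq_hz = 60e6) {
  stopifnot(numerical_aperture > 0, numerical_aperture <= 1,
            center_freq_hz > 0)
  0.71 * sound_speed_m_per_s / (numerical_aperture * center_freq_hz)
}

#' @rdname lateral_resolution
#' @param bw_3db_hz -3 dB detection bandwidth (Hz).
#' @export
axial_resolution <- function(sound_speed_m_per_s = 1500, bw_3db_hz = 115e6) {
  stopifnot(bw_3db_hz > 0)
  0.88 * sound_speed_m_per_s / bw_3db_hz
}
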