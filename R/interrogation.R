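# Parallel interrogation loop: comb through the pressure-modulated array,
# coherent detection with calibrated noise, per-frame FFT demodulation, and
# Lorentzian resonance tracking back to per-ring pressure waveforms.

#' Receiver noise specification
#'
#' Additive white Gaussian noise at the coherent receiver, expressed relative
#' to the RMS of the transmitted comb frame: each measured complex sample
#' gets independent real/imaginary noise of standard deviation
#' \code{sigma_rel * rms(frame)}. The default is calibrated once so that the
#' parallel-mode pressure noise floor of the default 15-ring array sits at
#' the 36.9 Pa / 20 MHz noise-equivalent-pressure scale.
#'
#' @param sigma_rel Relative noise level per complex component.
#' @param seed RNG seed used for every noise draw.
#' @param nep_target_pa Optional integrated-NEP calibration target (Pa in the
#'   stated band), recorded for provenance and used by
#'   \code{\link{calibrate_receiver_noise}}.
#' @param nep_band_hz Band over which \code{nep_target_pa} is integrated.
#' @return An object of class \code{noise_spec}.
#' @export
noise_spec <- function(sigma_rel = 0.00436, seed = 1L,
                       nep_target_pa = 36.9, nep_band_hz = 20e6) {
  stopifnot(sigma_rel >= 0)
  structure(list(sigma_rel = sigma_rel, seed = as.integer(seed),
                 nep_target_pa = nep_target_pa, nep_band_hz = nep_band_hz),
            class = "noise_spec")
}

# Resample a per-ring pressure matrix onto the comb frame grid, with an
# aliasing check against the per-ring Nyquist limit (tooth spacing / 2).
frames_from_records <- function(records, n_rings, frame_rate_hz, n_frames,
                                on_alias = c("warn", "error"),
                                band_limit = FALSE) {
  on_alias <- match.arg(on_alias)
  if (is.matrix(records)) {
    p <- records
    fs <- attr(records, "fs_hz") %||% frame_rate_hz
    times <- (0:(ncol(p) - 1)) / fs
  } else if (inherits(records, "pressure_records")) {
    d <- dim(records$pressures_pa)
    if (d[1] != 1) stop("interrogation consumes a single acquisition step")
    p <- matrix(records$pressures_pa[1, , ], nrow = d[2])
    fs <- records$fs_hz
    times <- records$times_s - records$times_s[1]
  } else stop("records must be a matrix or pressure_records")
  if (nrow(p) != n_rings) {
    stop("records have ", nrow(p), " channels but the array has ", n_rings,
         " rings")
  }
  if (band_limit && fs > frame_rate_hz * (1 + 1e-9)) {
    # brickwall low-pass at the post-demodulation Nyquist before decimation
    f <- abs(fft_freqs(ncol(p), fs))
    for (i in seq_len(nrow(p))) {
      X <- stats::fft(p[i, ])
      X[f > frame_rate_hz / 2] <- 0
      p[i, ] <- Re(stats::fft(X, inverse = TRUE) / length(X))
    }
  }
  if (fs > frame_rate_hz * (1 + 1e-9)) {
    # check spectral content above the post-demodulation Nyquist
    for (i in seq_len(nrow(p))) {
      X <- Mod(stats::fft(p[i, ]))
      f <- abs(fft_freqs(length(X), fs))
      hi <- sum(X[f > frame_rate_hz / 2]^2); tot <- sum(X^2)
      if (tot > 0 && hi / tot > 1e-6) {
        msg <- sprintf(
          "ring %d pressure has %.2g%% of its energy above the %.2f MHz detection limit",
          i, 100 * hi / tot, frame_rate_hz / 2e6)
        if (on_alias == "error") stop(msg) else warning(msg)
        break
      }
    }
  }
  ft <- (seq_len(n_frames) - 1) / frame_rate_hz
  out <- matrix(0, nrow = n_rings, ncol = n_frames)
  for (i in seq_len(n_rings)) {
    out[i, ] <- stats::approx(times, p[i, ], xout = ft, rule = 2)$y
  }
  out
}

#' Interrogate the array with the comb
#'
#' Propagates the comb through the array frame by frame under the
#' quasi-static approximation: within each 25.6-ns frame the per-ring
#' pressures are held constant, each tooth is multiplied by the array
#' transmission at its frequency, and the coherent-receiver output is the
#' inverse transform of the modulated teeth plus additive complex white
#' Gaussian noise.
#'
#' @param array A \code{ring_array}.
#' @param records Per-ring pressure input: a \code{pressure_records} with one
#'   acquisition step and one channel per ring, or a numeric matrix
#'   (rings x samples, attribute \code{fs_hz} giving its rate; defaults to
#'   the frame rate).
#' @param comb A \code{comb_waveform}.
#' @param noise A \code{noise_spec}.
#' @param n_frames Number of frames; default covers the record duration.
#' @param on_alias "warn" (default) or "error" when the pressure input has
#'   spectral content above half the tooth spacing.
#' @param band_limit Brickwall low-pass the records at half the tooth
#'   spacing before decimating to the frame grid (the anti-alias filter of
#'   DOFC-mode acquisition); default FALSE, leaving the contract check to
#'   \code{on_alias}.
#' @return An object of class \code{dofc_measurement}: complex sample matrix
#'   (\code{n_subcarriers} x frames) plus the comb reference and metadata.
#' @export
interrogate <- function(array, records, comb, noise = noise_spec(),
                        n_frames = NULL, on_alias = c("warn", "error"),
                        band_limit = FALSE) {
  stopifnot(inherits(array, "ring_array"), inherits(comb, "comb_waveform"))
  spec <- comb$spec
  frate <- tooth_spacing(spec)
  nr <- length(array$rings)
  if (is.null(n_frames)) {
    dur <- if (is.matrix(records)) {
      fs <- attr(records, "fs_hz") %||% frate
      ncol(records) / fs
    } else diff(range(records$times_s)) + 1 / records$fs_hz
    n_frames <- max(1L, floor(dur * frate))
  }
  pmat <- frames_from_records(records, nr, frate, n_frames,
                              match.arg(on_alias), band_limit = band_limit)
  occ <- spec$occupied
  f_occ <- spec$freqs_hz[occ]
  sens <- vapply(array$rings, `[[`, numeric(1), "sensitivity_hz_per_pa")
  c0 <- ring_centers(array)
  fw <- fwhm_from_q(vapply(array$rings, `[[`, numeric(1), "q_factor"),
                    array$optical_carrier_hz)
  dep <- vapply(array$rings, `[[`, numeric(1), "dip_depth")

  # transmission per occupied tooth per frame (product over rings)
  TT <- matrix(1, nrow = length(occ), ncol = n_frames)
  for (i in seq_len(nr)) {
    centers <- c0[i] + sens[i] * pmat[i, ]          # length n_frames
    hw2 <- (fw[i] / 2)^2
    D <- outer(f_occ, centers, `-`)
    TT <- TT * (1 - dep[i] * hw2 / (D^2 + hw2))
  }
  Y <- matrix(0i, nrow = spec$n_subcarriers, ncol = n_frames)
  Y[occ, ] <- comb$teeth[occ] * TT
  samples <- stats::mvfft(Y, inverse = TRUE) / spec$n_subcarriers
  if (noise$sigma_rel > 0) {
    sd_abs <- noise$sigma_rel * sqrt(mean(Mod(comb$samples)^2))
    ntot <- length(samples)
    samples <- samples + with_seed(noise$seed,
      complex(real = stats::rnorm(ntot, 0, sd_abs),
              imaginary = stats::rnorm(ntot, 0, sd_abs)))
  }
  structure(list(samples = samples, comb = comb, noise = noise,
                 frame_rate_hz = frate, n_frames = n_frames,
                 array_carrier_hz = array$optical_carrier_hz),
            class = "dofc_measurement")
}

#' @export
print.dofc_measurement <- function(x, ...) {
  cat(sprintf("<dofc_measurement> %d frames x %d samples (%.2f us)\n",
              x$n_frames, nrow(x$samples), x$n_frames / x$frame_rate_hz * 1e6))
  invisible(x)
}

#' Demodulate measured frames into a spectrogram
#'
#' Per-frame DFT of the measured samples, with each tooth normalized by the
#' stored no-array reference frame, yielding the array transmission per
#' tooth per frame -- the spectrogram of dip tracks versus time.
#'
#' @param measured A \code{dofc_measurement}, or a complex sample matrix
#'   (\code{n_subcarriers} x frames).
#' @param spec A \code{comb_spec}; taken from \code{measured} when omitted.
#' @param reference Complex reference teeth (the calibration frame); taken
#'   from the embedded comb when omitted. An error results if neither is
#'   available.
#' @param magnitude Return magnitude transmission (default) rather than the
#'   complex ratio.
#' @return An object of class \code{spectrogram}: \code{freq_offsets_hz}
#'   (ascending tooth grid), \code{times_s} (frame starts), and
#'   \code{transmission} (teeth x frames).
#' @export
demodulate_frames <- function(measured, spec = NULL, reference = NULL,
                              magnitude = TRUE) {
  if (inherits(measured, "dofc_measurement")) {
    spec <- spec %||% measured$comb$spec
    reference <- reference %||% measured$comb$teeth
    samples <- measured$samples
  } else {
    samples <- measured
  }
  if (is.null(spec)) stop("a comb_spec is required")
  if (is.null(reference)) {
    stop("no reference calibration frame: demodulation needs the no-array ",
         "comb teeth (run synthesize_comb and pass 'reference')")
  }
  if (!is.matrix(samples)) {
    if (length(samples) %% spec$n_subcarriers != 0) {
      stop("sample count is not an integer number of frames")
    }
    samples <- matrix(samples, nrow = spec$n_subcarriers)
  }
  if (nrow(samples) != spec$n_subcarriers) {
    stop("frame length ", nrow(samples), " does not match n_subcarriers ",
         spec$n_subcarriers)
  }
  Yh <- stats::mvfft(samples)
  occ <- spec$occupied
  ratio <- Yh[occ, , drop = FALSE] / reference[occ]
  ord <- order(spec$freqs_hz[occ])
  tr <- ratio[ord, , drop = FALSE]
  if (magnitude) tr <- Mod(tr)
  structure(list(freq_offsets_hz = spec$freqs_hz[occ][ord],
                 times_s = (0:(ncol(tr) - 1)) / tooth_spacing(spec),
                 transmission = tr,
                 frame_rate_hz = tooth_spacing(spec)),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d teeth x %d frames, %.4f MHz tooth grid\n",
              nrow(x$transmission), ncol(x$transmission),
              diff(x$freq_offsets_hz[1:2]) / 1e6))
  invisible(x)
}

#' Track resonance dips through a spectrogram
#'
#' For each ring and each frame, fits the comb teeth inside a window around
#' the tuned center to a Lorentzian dip and returns the dip center. The
#' default fitter uses the exact reciprocal form of the Lorentzian deficit:
#' for \eqn{T(f) = 1 - d\,hw^2/((f-c)^2 + hw^2)}, the quantity
#' \eqn{1/(1-T)} is an exact quadratic in \eqn{f}, so a weighted quadratic
#' least-squares fit recovers the center in closed form (exact at zero
#' noise) and vectorizes over frames. Teeth are first normalized by the
#' null-case contribution of the other rings. Optionally a
#' Levenberg-Marquardt refinement polishes each frame's fit.
#'
#' Frames whose fitted center leaves the window are flagged and interpolated
#' from neighbours; if more than \code{max_out_fraction} of a ring's frames
#' are out of window, a tracking error naming the ring is raised.
#'
#' @param spectrogram A \code{spectrogram}.
#' @param array The \code{ring_array} that produced it.
#' @param window_hz Half-width of the fit window around each tuned center;
#'   default half the array spacing.
#' @param refine Run a per-frame Levenberg-Marquardt Lorentzian refinement
#'   (slower; default FALSE).
#' @param max_out_fraction Tracking-error threshold on the fraction of
#'   out-of-window frames per ring.
#' @return An object of class \code{pa_waveforms}: \code{times_s},
#'   \code{shifts_hz} and \code{pressures_pa} (frames x rings),
#'   \code{ring_labels}, \code{sample_rate_hz} (= tooth spacing) and
#'   \code{n_flagged} per ring.
#' @export
fit_dips <- function(spectrogram, array, window_hz = NULL, refine = FALSE,
                     max_out_fraction = 0.25) {
  stopifnot(inherits(spectrogram, "spectrogram"), inherits(array, "ring_array"))
  f <- spectrogram$freq_offsets_hz
  TRm <- spectrogram$transmission
  nF <- ncol(TRm)
  nr <- length(array$rings)
  if (is.null(window_hz)) {
    window_hz <- if (!is.null(array$spacing_hz)) array$spacing_hz / 2 else
      5 * fwhm_from_q(array$rings[[1]]$q_factor, array$optical_carrier_hz)
  }
  c0 <- ring_centers(array)
  shifts <- matrix(NA_real_, nF, nr)
  n_flagged <- integer(nr)

  for (i in seq_len(nr)) {
    r <- array$rings[[i]]
    sel <- which(abs(f - c0[i]) <= window_hz)
    if (length(sel) < 3) {
      stop("ring ", i, " covered by fewer than 3 comb teeth in its window")
    }
    fw <- fwhm_from_q(r$q_factor, array$optical_carrier_hz)
    # divide out the other rings' null-case dips
    other <- rep(1, length(sel))
    for (k in seq_len(nr)[-i]) {
      rk <- array$rings[[k]]
      other <- other * lorentzian_dip(
        f[sel], c0[k], fwhm_from_q(rk$q_factor, array$optical_carrier_hz),
        rk$dip_depth)
    }
    y <- 1 - sweep(TRm[sel, , drop = FALSE], 1, other, `/`)
    y[y < 1e-9] <- 1e-9
    # fixed weights from the null-case line shape: var(1/y) ~ sigma^2 / y^4
    L0 <- 1 - lorentzian_dip(f[sel], c0[i], fw, r$dip_depth)
    w <- L0^4
    u <- (f[sel] - c0[i]) / 1e9                    # GHz units, conditioning
    X <- cbind(1, u, u^2)
    XtW <- t(X * w)
    Mproj <- solve(XtW %*% X, XtW)                 # 3 x npts, frame-invariant
    beta <- Mproj %*% (1 / y)                      # 3 x nF
    ctr <- -beta[2, ] / (2 * beta[3, ])            # GHz
    bad <- !is.finite(ctr) | beta[3, ] <= 0 | abs(ctr) > window_hz / 1e9
    n_out <- sum(!is.finite(ctr) | abs(ctr) > window_hz / 1e9)
    if (n_out > max_out_fraction * nF) {
      stop(sprintf(
        "tracking error: ring %d dip out of its +/-%.0f MHz window in %d/%d frames",
        i, window_hz / 1e6, n_out, nF))
    }
    if (any(bad)) {
      n_flagged[i] <- sum(bad)
      idx <- which(!bad)
      if (length(idx) >= 2) {
        ctr[bad] <- stats::approx(idx, ctr[idx], xout = which(bad),
                                  rule = 2)$y
      } else ctr[bad] <- 0
      message(sprintf("ring %d: %d frame(s) flagged and interpolated",
                      i, n_flagged[i]))
    }
    sh <- ctr * 1e9
    if (refine) sh <- refine_dip_fits(f[sel], y, c0[i], sh, fw, r$dip_depth)
    shifts[, i] <- sh
  }
  sens <- vapply(array$rings, `[[`, numeric(1), "sensitivity_hz_per_pa")
  structure(list(times_s = spectrogram$times_s,
                 shifts_hz = shifts,
                 pressures_pa = sweep(shifts, 2, sens, `/`),
                 ring_labels = seq_len(nr),
                 sample_rate_hz = spectrogram$frame_rate_hz,
                 n_flagged = n_flagged),
            class = "pa_waveforms")
}

# Levenberg-Marquardt polish of per-frame dip centers (minpack.lm).
refine_dip_fits <- function(fsel, y, c0, shifts, fwhm0, depth0) {
  out <- shifts
  for (j in seq_len(ncol(y))) {
    yy <- y[, j]
    fit <- try(minpack.lm::nlsLM(
      yy ~ d * (hw^2) / ((fsel - (c0 + s))^2 + hw^2),
      start = list(d = depth0, hw = fwhm0 / 2, s = shifts[j]),
      control = minpack.lm::nls.lm.control(maxiter = 30)), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      out[j] <- stats::coef(fit)[["s"]]
    }
  }
  out
}

#' @export
print.pa_waveforms <- function(x, ...) {
  cat(sprintf("<pa_waveforms> %d rings x %d frames @ %.4f MS/s\n",
              ncol(x$shifts_hz), nrow(x$shifts_hz),
              x$sample_rate_hz / 1e6))
  invisible(x)
}

#' Export recovered waveforms to per-ring CSV
#' @param waves A \code{pa_waveforms}.
#' @param path Output CSV (time plus one pressure column per ring).
#' @return \code{path}, invisibly.
#' @export
export_waveforms_csv <- function(waves, path) {
  df <- data.frame(time_s = waves$times_s, waves$pressures_pa)
  names(df) <- c("time_s", paste0("ring_", waves$ring_labels))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Single-ring wideband (direct) interrogation
#'
#' Continuous-wave edge detection on one ring: the laser sits on the dip
#' flank at \code{bias_offset_hz} from the (null) resonance and the detected
#' transmission follows the pressure-shifted Lorentzian, preserving the full
#' acoustic bandwidth (no comb, no frame-rate limit). The default bias is
#' the maximum-slope point of the dip flank, at \code{FWHM / (2*sqrt(3))}
#' from center.
#'
#' @param ring A \code{ring_resonance}.
#' @param record Pressure time series (Pa).
#' @param noise A \code{noise_spec}; \code{sigma_rel} is applied as additive
#'   transmission noise per sample.
#' @param fs_hz Sampling rate of \code{record}.
#' @param bias_offset_hz Laser detuning from the null resonance center (Hz).
#' @param optical_carrier_hz Optical carrier (Hz).
#' @return List with \code{output} (transmission time series),
#'   \code{chain_sensitivity} (transmission units per Pa at the bias point),
#'   \code{bias_offset_hz} and \code{fs_hz}.
#' @export
direct_interrogate <- function(ring, record, noise = noise_spec(),
                               fs_hz = 500e6, bias_offset_hz = NULL,
                               optical_carrier_hz = default_optical_carrier()) {
  stopifnot(inherits(ring, "ring_resonance"))
  fw <- fwhm_from_q(ring$q_factor, optical_carrier_hz)
  hw <- fw / 2
  if (is.null(bias_offset_hz)) bias_offset_hz <- hw / sqrt(3)
  if (abs(bias_offset_hz) < fw * 1e-6) {
    stop("bias point at the dip extremum has zero slope; detune the laser")
  }
  slope <- dip_slope(ring, bias_offset_hz, optical_carrier_hz)
  centers <- ring$center_offset_hz + ring$sensitivity_hz_per_pa * record
  f_laser <- ring$center_offset_hz + bias_offset_hz
  out <- lorentzian_dip(f_laser, centers, fw, ring$dip_depth)
  if (noise$sigma_rel > 0) {
    out <- out + with_seed(noise$seed,
                           stats::rnorm(length(out), 0, noise$sigma_rel))
  }
  list(output = out,
       chain_sensitivity = abs(slope) * ring$sensitivity_hz_per_pa,
       bias_offset_hz = bias_offset_hz, fs_hz = fs_hz)
}

#' Transmission slope of a dip flank
#'
#' Derivative dT/df of a ring's Lorentzian transmission at a detuning from
#' the dip center; used to choose the bias point of direct interrogation.
#'
#' @param ring A \code{ring_resonance}.
#' @param offset_hz Detuning from the dip center (Hz).
#' @param optical_carrier_hz Optical carrier (Hz).
#' @return Slope in transmission units per Hz.
#' @export
dip_slope <- function(ring, offset_hz,
                      optical_carrier_hz = default_optical_carrier()) {
  hw <- fwhm_from_q(ring$q_factor, optical_carrier_hz) / 2
  ring$dip_depth * hw^2 * 2 * offset_hz / (offset_hz^2 + hw^2)^2
}

#' Calibrate receiver noise to a pressure-noise target
#'
#' Runs a noise-only interrogation of the array and scales the receiver
#' noise level so the recovered pressure noise floor (RMS over the full
#' detection band) matches the integrated-NEP target of the noise spec.
#' Noise propagates linearly, so one measurement fixes the scale; a second
#' pass verifies it.
#'
#' @param array A \code{ring_array}.
#' @param comb A \code{comb_waveform}.
#' @param noise Starting \code{noise_spec} carrying the target.
#' @param n_frames Frames for the calibration run.
#' @return A \code{noise_spec} with calibrated \code{sigma_rel}.
#' @export
calibrate_receiver_noise <- function(array, comb, noise = noise_spec(),
                                     n_frames = 1024L) {
  target <- noise$nep_target_pa *
    sqrt((tooth_spacing(comb$spec) / 2) / noise$nep_band_hz)
  floor_rms <- function(ns) {
    m <- interrogate(array,
                     matrix(0, length(array$rings), n_frames),
                     comb, ns, n_frames = n_frames)
    w <- fit_dips(demodulate_frames(m), array)
    mean(apply(w$pressures_pa, 2, rms))
  }
  measured <- floor_rms(noise)
  out <- noise
  out$sigma_rel <- noise$sigma_rel * target / measured
  out
}
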