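# Digital optical frequency comb (DOFC): OFDM synthesis and spectral
# bookkeeping.

#' Comb specification
#'
#' Defines the digital optical frequency comb: an OFDM frame of
#' \code{n_subcarriers} complex baseband samples played at \code{dac_rate_hz},
#' giving a tooth spacing of \code{dac_rate_hz / n_subcarriers}
#' (39.0625 MHz at the 60 GHz / 1536 defaults) and a frame period of
#' \code{n_subcarriers / dac_rate_hz} (25.6 ns). Teeth populate the
#' \code{bandwidth_hz} band symmetrically about the carrier
#' (carrier-suppressed double sideband at complex baseband).
#'
#' @param n_subcarriers OFDM sequence length (default 1536).
#' @param dac_rate_hz DAC sampling rate (Hz, default 60 GHz).
#' @param bandwidth_hz Occupied analysis band (Hz, default 40 GHz); must not
#'   exceed \code{dac_rate_hz}.
#' @param phase_schedule Optional per-tooth phases (radians), one per
#'   occupied tooth in ascending frequency order. Default is the
#'   deterministic Newman quadratic schedule, which keeps the frame's
#'   peak-to-average power ratio below 4.
#' @param phase_seed If \code{phase_schedule = "random"}, seed for the
#'   pseudo-random schedule.
#' @param carrier_suppressed Zero the DC tooth (default TRUE).
#' @return An object of class \code{comb_spec}.
#' @export
comb_spec <- function(n_subcarriers = 1536L, dac_rate_hz = 60e9,
                      bandwidth_hz = 40e9, phase_schedule = NULL,
                      phase_seed = 7L, carrier_suppressed = TRUE) {
  n <- as.integer(n_subcarriers)
  stopifnot(n >= 1, dac_rate_hz > 0, bandwidth_hz > 0)
  if (bandwidth_hz > dac_rate_hz) {
    stop("occupied band exceeds the DAC band: bandwidth_hz must be <= dac_rate_hz")
  }
  spacing <- dac_rate_hz / n
  freqs <- fft_freqs(n, dac_rate_hz)
  occ <- which(abs(freqs) <= bandwidth_hz / 2 + spacing * 1e-9)
  if (carrier_suppressed) occ <- setdiff(occ, which(freqs == 0))
  ord <- occ[order(freqs[occ])]
  m <- length(ord)
  phases <-
    if (is.null(phase_schedule)) {
      pi * (seq_len(m) - 1)^2 / m            # Newman schedule
    } else if (identical(phase_schedule, "random")) {
      with_seed(phase_seed, stats::runif(m, 0, 2 * pi))
    } else {
      stopifnot(length(phase_schedule) == m)
      as.numeric(phase_schedule)
    }
  structure(
    list(n_subcarriers = n, dac_rate_hz = dac_rate_hz,
         bandwidth_hz = bandwidth_hz, tooth_spacing_hz = spacing,
         occupied = ord, freqs_hz = freqs, phases = phases,
         carrier_suppressed = isTRUE(carrier_suppressed),
         phase_seed = phase_seed),
    class = "comb_spec")
}

#' @export
print.comb_spec <- function(x, ...) {
  cat(sprintf(
    "<comb_spec> %d subcarriers @ %.1f GS/s, %d occupied teeth, spacing %.4f MHz\n",
    x$n_subcarriers, x$dac_rate_hz / 1e9, length(x$occupied),
    x$tooth_spacing_hz / 1e6))
  invisible(x)
}

#' Comb tooth spacing
#'
#' @param spec A \code{comb_spec}.
#' @return \code{dac_rate_hz / n_subcarriers} in Hz.
#' @examples
#' tooth_spacing(comb_spec()) / 1e6  # 39.0625
#' @export
tooth_spacing <- function(spec) {
  stopifnot(inherits(spec, "comb_spec"))
  spec$dac_rate_hz / spec$n_subcarriers
}

#' Frame duration of a comb spec (s)
#' @param spec A \code{comb_spec}.
#' @return \code{n_subcarriers / dac_rate_hz}; 25.6 ns at defaults.
#' @export
frame_duration <- function(spec) {
  stopifnot(inherits(spec, "comb_spec"))
  spec$n_subcarriers / spec$dac_rate_hz
}

#' Synthesize one comb frame
#'
#' Inverse DFT of unit-magnitude subcarriers with the spec's phase schedule
#' over the occupied band; the DC bin is zeroed when carrier suppression is
#' on. The frame is periodic with the frame duration, so the spectrum of any
#' repetition is supported only on multiples of the tooth spacing.
#'
#' @param spec A \code{comb_spec}.
#' @return An object of class \code{comb_waveform} with fields
#'   \code{samples} (complex, length \code{n_subcarriers}), \code{teeth}
#'   (complex spectrum, FFT order) and \code{spec}.
#' @export
synthesize_comb <- function(spec = comb_spec()) {
  stopifnot(inherits(spec, "comb_spec"))
  n <- spec$n_subcarriers
  teeth <- complex(n)
  teeth[spec$occupied] <- exp(1i * spec$phases)
  samples <- stats::fft(teeth, inverse = TRUE) / n
  structure(list(samples = samples, teeth = teeth, spec = spec),
            class = "comb_waveform")
}

#' @export
print.comb_waveform <- function(x, ...) {
  p <- Mod(x$samples)^2
  cat(sprintf("<comb_waveform> %d samples, PAPR %.2f\n",
              length(x$samples), max(p) / mean(p)))
  invisible(x)
}

#' Per-tooth power fraction of a comb
#'
#' Fraction of the total frame power carried by each occupied tooth; for a
#' flat comb this is 1/(number of occupied teeth), e.g. 1/1536 when the full
#' DAC band is populated.
#'
#' @param wave A \code{comb_waveform}.
#' @return Numeric vector over occupied teeth.
#' @export
tooth_power_fraction <- function(wave) {
  stopifnot(inherits(wave, "comb_waveform"))
  p <- Mod(wave$teeth[wave$spec$occupied])^2
  p / sum(p)
}

#' Export a comb waveform as text
#'
#' Interleaved real/imaginary CSV of one frame, for inspection.
#' @param wave A \code{comb_waveform}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
export_comb_waveform <- function(wave, path) {
  stopifnot(inherits(wave, "comb_waveform"))
  utils::write.csv(
    data.frame(sample = seq_along(wave$samples) - 1L,
               re = Re(wave$samples), im = Im(wave$samples)),
    path, row.names = FALSE)
  invisible(path)
}
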