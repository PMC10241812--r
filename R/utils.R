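# Internal helpers shared across modules.

# Speed of light in vacuum (m/s), used for all optical frequency/wavelength
# conversions.
.C_LIGHT <- 299792458

# Optical carrier at the 1550 nm telecom wavelength (Hz).
default_optical_carrier <- function() .C_LIGHT / 1550e-9

#' Convert a frequency span to a wavelength span
#'
#' Converts a small optical frequency interval \code{delta_f_hz} around a
#' carrier wavelength into the corresponding wavelength interval, using the
#' first-order relation \eqn{\Delta\lambda = \lambda^2 \Delta f / c}.
#'
#' @param delta_f_hz Frequency span in Hz (non-negative).
#' @param wavelength_m Carrier wavelength in metres (default 1550 nm).
#' @return Wavelength span in metres.
#' @examples
#' hz_to_wavelength_span(40e9) * 1e12   # ~320 pm at 1550 nm
#' @export
hz_to_wavelength_span <- function(delta_f_hz, wavelength_m = 1550e-9) {
  stopifnot(is.numeric(delta_f_hz), is.numeric(wavelength_m))
  if (any(delta_f_hz < 0) || any(wavelength_m <= 0)) {
    stop("delta_f_hz must be >= 0 and wavelength_m > 0")
  }
  wavelength_m^2 * delta_f_hz / .C_LIGHT
}

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Signed FFT bin frequencies (Hz) for an n-point transform at sample rate fs:
# 0, fs/n, ..., then the negative half, in FFT storage order.
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k * fs / n
}

# Discrete analytic-signal envelope of a real series via the FFT Hilbert
# transform.
hilbert_envelope <- function(x) {
  n <- length(x)
  if (n < 2) return(abs(x))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Linear-interpolated full width at `frac` of the maximum of profile y(x).
# Errors if the profile never falls below frac * max on either side.
width_at_fraction <- function(x, y, frac = 0.5) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  i0 <- which.max(y)
  half <- frac * y[i0]
  left <- NA_real_
  if (i0 > 1) for (i in i0:2) {
    if (y[i - 1] < half) {
      left <- x[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (x[i] - x[i - 1])
      break
    }
  }
  right <- NA_real_
  if (i0 < length(y)) for (i in i0:(length(y) - 1)) {
    if (y[i + 1] < half) {
      right <- x[i] + (y[i] - half) / (y[i] - y[i + 1]) * (x[i + 1] - x[i])
      break
    }
  }
  if (is.na(left) || is.na(right)) {
    stop("profile never falls below ", frac, " of its maximum on both sides")
  }
  right - left
}

rms <- function(x) sqrt(mean(x^2))

# 2D rotation of an n x 2 matrix of points about a center, angle in degrees
# (counterclockwise positive).
rotate_points <- function(p, angle_deg, center = c(0, 0)) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(p, 2, center) %*% t(R), 2, center, `+`)
}
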