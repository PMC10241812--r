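# Micro-ring sensor array: Lorentzian transmission model, resonance
# assignment, and spectrum-capacity arithmetic.

#' Single micro-ring resonance
#'
#' Describes one micro-ring as a Lorentzian transmission dip on the bus
#' waveguide: a resonance at \code{center_offset_hz} from the comb center,
#' quality factor \code{q_factor}, fractional dip depth, and a linear
#' pressure-to-frequency-shift sensitivity.
#'
#' @param center_offset_hz Resonant-frequency offset from the comb center (Hz).
#' @param q_factor Dimensionless quality factor (> 0). The fabricated rings
#'   this models have Q between 5e5 and 7e5.
#' @param dip_depth Fractional transmission drop at resonance, in (0, 1].
#' @param sensitivity_hz_per_pa Resonance shift per unit pressure (Hz/Pa).
#'   Not a published quantity; treated as a free calibration parameter.
#' @param label Integer index of the ring in the array.
#' @return An object of class \code{ring_resonance}.
#' @export
ring_resonance <- function(center_offset_hz, q_factor, dip_depth = 0.9,
                           sensitivity_hz_per_pa = 1e4, label = 1L) {
  stopifnot(is.numeric(center_offset_hz), length(center_offset_hz) == 1)
  if (!is.finite(q_factor) || q_factor <= 0) stop("q_factor must be > 0")
  if (!is.finite(dip_depth) || dip_depth <= 0 || dip_depth > 1) {
    stop("dip_depth must lie in (0, 1]")
  }
  if (!is.finite(sensitivity_hz_per_pa)) stop("sensitivity must be finite")
  structure(
    list(center_offset_hz = center_offset_hz, q_factor = q_factor,
         dip_depth = dip_depth,
         sensitivity_hz_per_pa = sensitivity_hz_per_pa,
         label = as.integer(label)),
    class = "ring_resonance")
}

#' Micro-ring sensor array specification
#'
#' An ordered collection of \code{\link{ring_resonance}} dips sharing one
#' optical carrier. Ring center offsets must be strictly increasing with
#' label, the ordering the photosensitive tuning step establishes.
#'
#' @param rings List of \code{ring_resonance} objects.
#' @param optical_carrier_hz Absolute optical frequency of the comb center
#'   (Hz); defaults to the 1550 nm carrier.
#' @param spacing_hz Target adjacent-resonance separation (Hz), if the array
#'   was laid out on a regular grid; used as the default dip-fit window scale.
#' @return An object of class \code{ring_array}.
#' @export
ring_array <- function(rings, optical_carrier_hz = default_optical_carrier(),
                       spacing_hz = NULL) {
  stopifnot(length(rings) >= 1,
            all(vapply(rings, inherits, logical(1), "ring_resonance")))
  centers <- vapply(rings, `[[`, numeric(1), "center_offset_hz")
  if (length(centers) > 1 && any(diff(centers) <= 0)) {
    stop("ring center offsets must be strictly increasing with label")
  }
  if (optical_carrier_hz <= 0) stop("optical_carrier_hz must be > 0")
  if (is.null(spacing_hz) && length(centers) > 1) {
    spacing_hz <- mean(diff(centers))
  }
  structure(
    list(rings = rings, optical_carrier_hz = optical_carrier_hz,
         spacing_hz = spacing_hz),
    class = "ring_array")
}

#' @export
print.ring_array <- function(x, ...) {
  centers <- ring_centers(x)
  cat(sprintf("<ring_array> %d rings, carrier %.4f THz\n",
              length(x$rings), x$optical_carrier_hz / 1e12))
  cat(sprintf("  offsets: %.3f .. %.3f GHz", min(centers) / 1e9,
              max(centers) / 1e9))
  if (!is.null(x$spacing_hz)) {
    cat(sprintf(" (spacing %.3f GHz)", x$spacing_hz / 1e9))
  }
  cat("\n")
  invisible(x)
}

#' Ring center offsets of an array
#' @param array A \code{ring_array}.
#' @return Numeric vector of center offsets (Hz), ordered by label.
#' @export
ring_centers <- function(array) {
  vapply(array$rings, `[[`, numeric(1), "center_offset_hz")
}

#' Resonance linewidth from the quality factor
#'
#' Full width at half maximum of a resonance, \eqn{FWHM = f_{carrier} / Q}.
#' For Q between 5e5 and 7e5 at 1550 nm this gives linewidths of roughly
#' 277--387 MHz.
#'
#' @param q_factor Quality factor (> 0).
#' @param optical_carrier_hz Absolute optical carrier frequency (Hz).
#' @return FWHM in Hz.
#' @examples
#' fwhm_from_q(5e5) / 1e6  # ~386.8 MHz
#' @export
fwhm_from_q <- function(q_factor, optical_carrier_hz = default_optical_carrier()) {
  if (any(q_factor <= 0) || any(optical_carrier_hz <= 0)) {
    stop("q_factor and optical_carrier_hz must be > 0")
  }
  optical_carrier_hz / q_factor
}

# Lorentzian transmission of a single dip: 1 - d * hw^2 / ((f - c)^2 + hw^2),
# hw = FWHM/2. Vectorized over f (and over c if f is scalar).
lorentzian_dip <- function(f, center, fwhm, depth) {
  hw <- fwhm / 2
  1 - depth * hw^2 / ((f - center)^2 + hw^2)
}

#' Array transmission spectrum under acoustic load
#'
#' Evaluates the bus-waveguide transmission of the array on a frequency grid.
#' Each ring contributes a symmetric Lorentzian dip centered at its tuned
#' offset plus \code{sensitivity * pressure}; independent rings on one bus
#' combine multiplicatively.
#'
#' @param array A \code{ring_array}.
#' @param freq_grid_hz Monotone vector of frequency offsets from the comb
#'   center (Hz).
#' @param pressures_pa Acoustic pressure per ring (Pa); scalar 0 recycles.
#' @return Numeric vector of transmission values in (0, 1].
#' @export
transmission_spectrum <- function(array, freq_grid_hz, pressures_pa = 0) {
  stopifnot(inherits(array, "ring_array"))
  if (is.unsorted(freq_grid_hz, strictly = FALSE)) {
    stop("freq_grid_hz must be monotone non-decreasing")
  }
  n <- length(array$rings)
  if (length(pressures_pa) == 1) pressures_pa <- rep(pressures_pa, n)
  if (length(pressures_pa) != n) {
    stop("need one pressure per ring (", n, "), got ", length(pressures_pa))
  }
  tr <- rep(1, length(freq_grid_hz))
  for (i in seq_len(n)) {
    r <- array$rings[[i]]
    c_i <- r$center_offset_hz + r$sensitivity_hz_per_pa * pressures_pa[i]
    tr <- tr * lorentzian_dip(freq_grid_hz, c_i,
                              fwhm_from_q(r$q_factor, array$optical_carrier_hz),
                              r$dip_depth)
  }
  tr
}

#' Lay out ordered, equally spaced resonances in a band
#'
#' Places \code{n_rings} resonances on an arithmetic grid with separation
#' \code{spacing_hz}, symmetric about the band midpoint unless
#' \code{start_offset_hz} is given. Mirrors the post-tuning state of the
#' fabricated array: ordered with label, equally spaced (1.66 GHz average
#' separation for the 15-ring device).
#'
#' @param n_rings Number of rings (>= 1).
#' @param spacing_hz Adjacent-resonance separation (Hz).
#' @param band_hz Length-2 analysis band (Hz offsets from comb center).
#' @param q_factors Per-ring quality factors; default spreads 5e5..7e5.
#' @param dip_depth,sensitivity_hz_per_pa Passed to \code{\link{ring_resonance}}.
#' @param margin_hz Edge margin kept free on each side of the band; defaults
#'   to half the FWHM of the median-Q ring, a guard against demodulation edge
#'   effects.
#' @param start_offset_hz Optional explicit offset of ring 1 (Hz).
#' @param optical_carrier_hz Optical carrier (Hz).
#' @return A \code{ring_array}.
#' @examples
#' arr <- assign_resonances(15, 1.66e9, c(-20e9, 20e9))
#' diff(range(ring_centers(arr))) / 1e9  # 23.24 GHz occupied span
#' @export
assign_resonances <- function(n_rings, spacing_hz, band_hz,
                              q_factors = NULL, dip_depth = 0.9,
                              sensitivity_hz_per_pa = 1e4,
                              margin_hz = NULL, start_offset_hz = NULL,
                              optical_carrier_hz = default_optical_carrier()) {
  stopifnot(n_rings >= 1, spacing_hz > 0, length(band_hz) == 2)
  band_hz <- sort(band_hz)
  if (is.null(q_factors)) {
    q_factors <- if (n_rings == 1) 6e5 else seq(5e5, 7e5, length.out = n_rings)
  }
  q_factors <- rep_len(q_factors, n_rings)
  if (is.null(margin_hz)) {
    margin_hz <- fwhm_from_q(stats::median(q_factors), optical_carrier_hz) / 2
  }
  usable <- diff(band_hz) - 2 * margin_hz
  if (usable <= 0) stop("band narrower than twice the edge margin")
  # Capacity rule: each ring occupies one spacing slot of spectrum.
  n_max <- floor(usable / spacing_hz)
  if (n_rings > n_max) {
    stop(sprintf(
      "band of %.3f GHz (margin %.3f GHz/side) holds at most %d rings at %.3f GHz spacing; %d requested",
      diff(band_hz) / 1e9, margin_hz / 1e9, n_max, spacing_hz / 1e9, n_rings))
  }
  centers <- if (!is.null(start_offset_hz)) {
    start_offset_hz + (seq_len(n_rings) - 1) * spacing_hz
  } else {
    mid <- mean(band_hz)
    mid + (seq_len(n_rings) - (n_rings + 1) / 2) * spacing_hz
  }
  if (centers[1] < band_hz[1] || centers[n_rings] > band_hz[2]) {
    stop("requested layout falls outside the analysis band")
  }
  rings <- lapply(seq_len(n_rings), function(i) {
    ring_resonance(centers[i], q_factors[i], dip_depth,
                   sensitivity_hz_per_pa, label = i)
  })
  ring_array(rings, optical_carrier_hz, spacing_hz)
}

#' Default 15-ring sensor array
#'
#' The tuned 15-element array: 1.66 GHz adjacent separation inside the 40 GHz
#' comb band, quality factors spread over 5e5..7e5, 0.9 dip depth.
#'
#' @param sensitivity_hz_per_pa Pressure sensitivity (Hz/Pa).
#' @return A \code{ring_array}.
#' @export
default_ring_array <- function(sensitivity_hz_per_pa = 1e4) {
  assign_resonances(15, 1.66e9, c(-20e9, 20e9),
                    sensitivity_hz_per_pa = sensitivity_hz_per_pa)
}

#' Ring capacity of a comb band
#'
#' How many rings an interrogation band can hold when each resonance is
#' allotted \code{spacing_hz} of spectrum: \code{floor(bandwidth / spacing)}.
#' 40 GHz at 1.66 GHz separation gives 24; at a 200 MHz allocation, 200.
#'
#' @param bandwidth_hz Comb analysis bandwidth (Hz).
#' @param spacing_hz Spectrum allocated per ring (Hz).
#' @return Integer ring count.
#' @export
max_rings_by_spacing <- function(bandwidth_hz, spacing_hz) {
  if (any(bandwidth_hz <= 0) || any(spacing_hz <= 0)) {
    stop("bandwidth_hz and spacing_hz must be > 0")
  }
  as.integer(floor(bandwidth_hz / spacing_hz))
}

#' Comb teeth sampling one resonance linewidth
#'
#' Number of comb teeth falling within one resonance FWHM,
#' \code{floor(fwhm / tooth_spacing)}; these are the sampling points the
#' Lorentzian dip fit uses. 7--9 teeth for Q of 7e5--5e5 at the default
#' 39.0625 MHz tooth spacing.
#'
#' @param fwhm_hz Resonance FWHM (Hz).
#' @param tooth_spacing_hz Comb tooth spacing (Hz).
#' @return Integer count.
#' @export
sampling_points_in_fwhm <- function(fwhm_hz, tooth_spacing_hz) {
  if (any(fwhm_hz <= 0) || any(tooth_spacing_hz <= 0)) {
    stop("fwhm_hz and tooth_spacing_hz must be > 0")
  }
  as.integer(floor(fwhm_hz / tooth_spacing_hz))
}

#' Write / read an array configuration
#'
#' Serializes per-ring center offset, Q, depth and sensitivity plus the
#' carrier to a YAML file; \code{read_ring_array} validates on load.
#'
#' @param array A \code{ring_array}.
#' @param path File path.
#' @return \code{write_ring_array} returns \code{path} invisibly;
#'   \code{read_ring_array} returns a \code{ring_array}.
#' @export
write_ring_array <- function(array, path) {
  stopifnot(inherits(array, "ring_array"))
  cfg <- list(
    optical_carrier_hz = array$optical_carrier_hz,
    spacing_hz = array$spacing_hz,
    rings = lapply(array$rings, function(r) {
      r[c("center_offset_hz", "q_factor", "dip_depth",
          "sensitivity_hz_per_pa", "label")]
    }))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_ring_array
#' @export
read_ring_array <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$rings)) stop("config has no 'rings' entry")
  rings <- lapply(cfg$rings, function(r) {
    do.call(ring_resonance, r[c("center_offset_hz", "q_factor", "dip_depth",
                                "sensitivity_hz_per_pa", "label")])
  })
  ring_array(rings,
             optical_carrier_hz = cfg$optical_carrier_hz %||% default_optical_carrier(),
             spacing_hz = cfg$spacing_hz)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a transmission spectrum as two-column text
#'
#' @param array A \code{ring_array}.
#' @param freq_grid_hz Frequency grid (Hz offsets).
#' @param path Output file (CSV: frequency_offset_hz, transmission).
#' @param pressures_pa Per-ring pressures (Pa).
#' @return \code{path}, invisibly.
#' @export
export_transmission <- function(array, freq_grid_hz, path, pressures_pa = 0) {
  tr <- transmission_spectrum(array, freq_grid_hz, pressures_pa)
  utils::write.csv(
    data.frame(frequency_offset_hz = freq_grid_hz, transmission = tr),
    path, row.names = FALSE)
  invisible(path)
}
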