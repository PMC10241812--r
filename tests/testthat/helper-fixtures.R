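# Shared fixtures, built in code at test time.

# Small comb for fast round trips: 256 subcarriers at 10 GS/s
# (tooth spacing 39.0625 MHz, same as the full comb).
small_comb_spec <- function() comb_spec(n_subcarriers = 256L, dac_rate_hz = 10e9,
                                        bandwidth_hz = 8e9)

# Three-ring array matched to the small comb band.
small_array <- function(sensitivity = 1e4) {
  assign_resonances(3, 1.66e9, c(-4e9, 4e9),
                    sensitivity_hz_per_pa = sensitivity)
}

# Band-limited multi-tone pressure matrix (rings x frames) at the frame
# rate, one distinct tone per ring, amplitude in Pa.
tone_pressures <- function(n_rings, n_frames, frame_rate_hz,
                           freqs_hz = (1:n_rings) * 2e6, amp_pa = 1e4) {
  t <- (0:(n_frames - 1)) / frame_rate_hz
  p <- t(vapply(seq_len(n_rings),
                function(i) amp_pa * sin(2 * pi * freqs_hz[i] * t),
                numeric(n_frames)))
  attr(p, "fs_hz") <- frame_rate_hz
  p
}

point_phantom <- function(x, y, signature = "gaussian_derivative",
                          amplitude = 1) {
  source_phantom(data.frame(x = x, y = y, radius = 0, amplitude = amplitude),
                 signature = signature, name = "point")
}
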