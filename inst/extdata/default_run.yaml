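# Default study configuration: 15-ring array interrogated by the
# 1536-subcarrier comb, moving-microsphere phantom.
seed: 1
array:
  n_rings: 15
  spacing_hz: 1.66e+9
  band_hz: [-2.0e+10, 2.0e+10]
  dip_depth: 0.9
  sensitivity_hz_per_pa: 1.0e+4
comb:
  n_subcarriers: 1536
  dac_rate_hz: 6.0e+10
  bandwidth_hz: 4.0e+10
medium:
  sound_speed_m_per_s: 1500
geometry:
  n_sensors: 15
  pitch_m: 4.0e-4
  mode: static
  schedule: [0.0]
phantom:
  name: microsphere
  speed_m_per_s: 4.8e-3
grid:
  xlim: [-5.0e-3, 5.0e-3]
  ylim: [0.0, 1.0e-2]
  pixel_m: 2.5e-5
duration_s: 8.0e-6
fs_hz: 5.0e+8
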