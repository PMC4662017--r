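# Phantom CMR protocol: bSSFP MOLLI at 1.5 T, simulated 60 bpm ECG.
tr_ms: 2.54
te_ms: 1.27
flip_deg: 35.0
ramp_pulses: 10
n_phase_encodes: 65
center_line_index: 33
slice_thickness_mm: 6.0
ir_pulse:
  shape: sech
  duration_ms: 4.74
  mu: 5.0
  beta_per_s: ~
  b1max_uT: ~
excitation_pulse:
  shape: sinc
  duration_us: 490
  lobes: 3
  apodization: hann
dt_us: 10
initial_tis_ms: [114.0, 350.0]
n_slice_spins: 21
slice_fov_factor: 2.0
scheme: 5(3p)3
rr_intervals_ms: [1000, 1000, 1000, 1000, 1000, 1000, 1000, 1000, 1000, 1000, 1000]
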