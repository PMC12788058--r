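# NaCl staircase demo: six flow-cell channels; channel 1 stays on water
# (blank), channels 2-6 step through identical 0-8% NaCl staircases
# (the span the LED window accommodates at this sensitivity).
# angle_deg is the initialization angle placing the water dip mid-band-1
# for the default stack (see solve_init_angle()).
width: 96
height: 64
n_channels: 6
angle_deg: 51.8262
frame_rate_s: 1
duration_s: 159
base_ri: 1.333
noise_sd: 0.002
seed: 7
courses:
  ch1: {type: constant, delta_riu: 0}
  ch2: {type: staircase, levels_nacl_percent: [0, 1, 2, 3, 4, 5, 6, 7], dwell_s: 20}
  ch3: {type: staircase, levels_nacl_percent: [0, 1, 2, 3, 4, 5, 6, 7], dwell_s: 20}
  ch4: {type: staircase, levels_nacl_percent: [0, 1, 2, 3, 4, 5, 6, 7], dwell_s: 20}
  ch5: {type: staircase, levels_nacl_percent: [0, 1, 2, 3, 4, 5, 6, 7], dwell_s: 20}
  ch6: {type: staircase, levels_nacl_percent: [0, 1, 2, 3, 4, 5, 6, 7], dwell_s: 20}
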