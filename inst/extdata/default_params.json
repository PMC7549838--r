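{
  "n": 100,
  "s_x1": 0.80,
  "s_x2": 0.02,
  "x_0": 1.00,
  "x_t": 0.20,
  "t_x": 0.20,
  "s_y1": 1.40,
  "s_y2": 0.28,
  "y_0": 3.50,
  "y_t": 1.20,
  "t_y": 0.20,
  "o_max": 45,
  "o_min": 45,
  "p": -0.01,
  "r_b": 1.00,
  "h_b": 0.50
}
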