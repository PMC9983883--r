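{
  "lambda": 0.005,
  "n_alpha": 7,
  "q": 0,
  "histeq": false,
  "beta": 1.2,
  "d_t": 20,
  "levels": [
    {"subsampling_factor": 4, "sigma": 2, "control_points": 8,  "iterations": 300, "sampling_fraction": 0.05, "d_max_per_diameter": 0.2, "step_size": 4, "momentum": 0.9,  "gw_m": 0.5, "gw_sigma": 1},
    {"subsampling_factor": 2, "sigma": 1, "control_points": 14, "iterations": 300, "sampling_fraction": 0.03, "d_max_per_diameter": 0.1, "step_size": 2, "momentum": 0.5,  "gw_m": 0.5, "gw_sigma": 2},
    {"subsampling_factor": 1, "sigma": 0, "control_points": 24, "iterations": 200, "sampling_fraction": 0.02, "d_max_per_diameter": 0.1, "step_size": 1, "momentum": 0.25, "gw_m": 0.5, "gw_sigma": 2}
  ]
}
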