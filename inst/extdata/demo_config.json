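{
  "seed": 1,
  "out_dir": "silknmr_demo_out",
  "stages": {
    "simulate": true,
    "relaxation": true,
    "shifts": true,
    "structure": true
  },
  "simulate": { "n_frames": 200 },
  "relaxation": { "freq_MHz": 600, "mc_reps": 100 },
  "shifts": { "csp_threshold_H": 0.03, "csp_threshold_N": 0.1 },
  "structure": { "ion_cutoff": 4.0, "shell_radius": 3.4 }
}
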