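{
  "preset": "desk_scale",
  "seed": 7,
  "simulation": {"bias": 600, "max_time": 1500},
  "dna": {"n_bp": 300, "nt_per_bead": 20},
  "detection": {"k_sigma": 5}
}
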