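{
  "kind": "perturb",
  "T": 25,
  "columns": [
    {"name": "immigration_shutdown", "disturbances": ["m0=0"]},
    {"name": "death_rate_increase", "disturbances": ["d0=0.25"]},
    {"name": "growth_rate_decrease", "disturbances": ["w0=0.95"]},
    {"name": "combined",
     "disturbances": ["mu=0.024", "m0=200", "d0=0.235", "w0=0.99"]}
  ]
}
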