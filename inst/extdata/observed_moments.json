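[
  {"species": "elephant", "setting": "captive", "mean_hours": 6.28, "sd_hours": 0.21},
  {"species": "elephant", "setting": "wild",    "mean_hours": 2.20, "sd_hours": 1.03},
  {"species": "sloth",    "setting": "captive", "mean_hours": 15.83, "sd_hours": 0.50},
  {"species": "sloth",    "setting": "wild",    "mean_hours": 9.63,  "sd_hours": 0.50}
]
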