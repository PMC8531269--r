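{
  "timing": { "TR": 2, "duration": 300 },
  "simulation": { "rate": 2.6, "noiseP": 0.5, "snr": 4 },
  "estimation": { "nPerm": 200 },
  "classifier": { "M": 51, "k": 5, "kernel": "coarse-gaussian" },
  "detection": { "alpha": 0.05 },
  "seed": 1
}
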