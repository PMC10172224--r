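{
  "control": {},
  "hbo_like": {
    "focus_peak_mean": {"nucleus": 128, "cytoplasm": 80},
    "cluster_lambda": {"perinuclear": 2.2, "nucleolar": 0.9}
  },
  "hypox_like": {
    "foci_lambda": {"nucleus": 5.4, "cytoplasm": 4.1},
    "focus_peak_mean": {"nucleus": 77, "cytoplasm": 70},
    "min_sep": 4,
    "cluster_lambda": {"perinuclear": 1.6, "nucleolar": 0.8}
  },
  "ir_like": {
    "foci_lambda": {"nucleus": 2.2, "cytoplasm": 1.6},
    "focus_peak_mean": {"nucleus": 35, "cytoplasm": 35},
    "cluster_lambda": {"perinuclear": 0.4, "nucleolar": 0.25}
  }
}
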