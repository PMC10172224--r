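{
  "manifest": {
    "condition": ["control", "control", "hbo_like", "hbo_like"],
    "dapi": ["data/control/field001_dapi.tif", "data/control/field002_dapi.tif",
             "data/hbo_like/field001_dapi.tif", "data/hbo_like/field002_dapi.tif"],
    "marker": ["data/control/field001_s96.tif", "data/control/field002_s96.tif",
               "data/hbo_like/field001_s96.tif", "data/hbo_like/field002_s96.tif"]
  },
  "output_dir": "results/run1",
  "control": "control",
  "pixel_size": 0.1,
  "params": {
    "nuclear_mode": "contrast_enhanced",
    "median_window": 3,
    "tophat_radius": 7,
    "cluster_area_threshold": 40
  },
  "m": 1
}
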