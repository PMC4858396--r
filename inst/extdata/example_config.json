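{
  "out_dir": "toxprofiler_example_out",
  "seed": 1,
  "stages": {
    "simulate": true,
    "curves": true,
    "curate": true,
    "profile": true,
    "qsar": true,
    "toxicophore": true
  },
  "simulation": {
    "n_compounds": 150,
    "n_assays": 12,
    "n_relevant_assays": 4,
    "association_odds": 8,
    "missing_rate": 0.3,
    "curve_noise_sd": 5
  },
  "curves": {
    "noise_threshold": 10
  },
  "profile": {
    "ra_threshold": 0.25
  },
  "qsar": {
    "ratio": 0.9375,
    "ad_k": 5,
    "ad_z": 0.5,
    "folds": 5
  },
  "toxicophore": {
    "min_support": 5,
    "top_fragments": 3
  },
  "inputs": {
    "smi": null,
    "curves_csv": null,
    "assay_matrix_csv": null,
    "labels_csv": null
  }
}
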