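{
  "observer": {
    "beta": 2,
    "k": 0.01,
    "sigma2": 0.0025,
    "prior_mean": 0,
    "signal_variance": 1
  },
  "n_trials": 100,
  "input_mean": 0,
  "input_sd": 1,
  "prior": {
    "mean": [0, 0],
    "sd": [10, 10],
    "noise": "fixed"
  },
  "candidates": [
    { "id": "informative_prior", "beta": 2, "k": 0.01, "sigma2": 0.0025, "prior_sd": 10 },
    { "id": "alternative", "beta": 0.5, "k": 0.02, "sigma2": 0.0025, "prior_sd": 10 }
  ]
}
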