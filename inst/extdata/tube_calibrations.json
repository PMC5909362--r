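{
  "Mo-Mo": {
    "alpha": 0.00997, "alpha_sigma": 0.00005,
    "beta": -0.186, "beta_sigma": 0.001,
    "Y0": 0.0938, "Y0_sigma": 0.0008,
    "reference_kvp": 28,
    "mu_en": 0.91, "mu_en_sigma": 0.04,
    "mu_en_by_kvp": {
      "kvp": [22, 24, 26, 28, 30],
      "mu_en": [1.04, 0.95, 0.89, 0.84, 0.81],
      "sigma": [0.05, 0.04, 0.04, 0.04, 0.03],
      "i0": [1.45, 2.05, 2.77, 3.55, 4.41]
    },
    "kvp_validity": [22, 34]
  },
  "Mo-Rh": {
    "alpha": 0.00892, "alpha_sigma": 0.00008,
    "beta": -0.180, "beta_sigma": 0.002,
    "Y0": 0.0739, "Y0_sigma": 0.0008,
    "reference_kvp": 28,
    "mu_en": 0.73, "mu_en_sigma": 0.02,
    "mu_en_by_kvp": {
      "kvp": [24, 26, 28, 30, 32],
      "mu_en": [0.80, 0.75, 0.72, 0.70, 0.68],
      "sigma": [0.03, 0.02, 0.02, 0.02, 0.02],
      "i0": [1.59, 2.22, 2.88, 3.62, 4.39]
    },
    "kvp_validity": [22, 34]
  },
  "Rh-Rh": {
    "alpha": 0.0078, "alpha_sigma": 0.0002,
    "beta": -0.149, "beta_sigma": 0.006,
    "Y0": 0.0707, "Y0_sigma": 0.0003,
    "reference_kvp": 28,
    "mu_en": 0.68, "mu_en_sigma": 0.04,
    "mu_en_by_kvp": {
      "kvp": [26, 28, 30, 32, 34],
      "mu_en": [0.76, 0.71, 0.67, 0.64, 0.61],
      "sigma": [0.04, 0.04, 0.04, 0.03, 0.03],
      "i0": [2.08, 2.69, 3.39, 4.1, 4.9]
    },
    "kvp_validity": [22, 34]
  },
  "W-Rh": {
    "alpha": 0.00271, "alpha_sigma": 0.00004,
    "beta": -0.047, "beta_sigma": 0.001,
    "Y0": 0.031, "Y0_sigma": 0.001,
    "reference_kvp": 28,
    "mu_en": 0.57, "mu_en_sigma": 0.02,
    "mu_en_by_kvp": {
      "kvp": [26, 28, 30, 32, 34],
      "mu_en": [0.61, 0.59, 0.56, 0.54, 0.53],
      "sigma": [0.02, 0.02, 0.02, 0.02, 0.02],
      "i0": [1.02, 1.25, 1.46, 1.68, 1.90]
    },
    "kvp_validity": [22, 34]
  },
  "W-Ag": {
    "alpha": 0.00371, "alpha_sigma": 0.00009,
    "beta": -0.066, "beta_sigma": 0.003,
    "Y0": 0.0391, "Y0_sigma": 0.0009,
    "reference_kvp": 28,
    "mu_en": 0.53, "mu_en_sigma": 0.02,
    "mu_en_by_kvp": {
      "kvp": [26, 28, 30, 32, 34],
      "mu_en": [0.58, 0.55, 0.52, 0.50, 0.48],
      "sigma": [0.02, 0.02, 0.03, 0.02, 0.02],
      "i0": [1.25, 1.59, 1.90, 2.21, 2.52]
    },
    "kvp_validity": [22, 34]
  }
}
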