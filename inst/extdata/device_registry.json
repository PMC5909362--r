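{
  "senographe-ds": {
    "FID_cm": 63.5,
    "yields": {
      "Mo-Mo": {"Y": 0.0938, "sigma": 0.0008},
      "Mo-Rh": {"Y": 0.0739, "sigma": 0.0008},
      "Rh-Rh": {"Y": 0.0707, "sigma": 0.0003}
    }
  }
}
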