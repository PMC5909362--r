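{
  "d": 0.5,
  "kvp": 0,
  "fid": 0,
  "note": "thickness tolerance from device manuals; calibration and yield sigmas come from the calibration set / registry"
}
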