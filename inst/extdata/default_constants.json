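{
  "fs": 600,
  "block_size": 30,
  "min_samples": 300,
  "max_buffer": 1800,
  "threshold": 0.3,
  "gaze_shift_s": 0.5,
  "front_end": {
    "notch": [48, 52],
    "bandpass": [2, 60],
    "order": 4
  },
  "low": {
    "frequencies": [6.67, 7.5, 8.57],
    "harmonics": 4,
    "subbands": [[2, 60], [12, 60], [20, 60]],
    "weight_a": 1.25,
    "weight_b": 0.25
  },
  "high": {
    "frequencies": [36, 40, 45],
    "harmonics": 1,
    "subbands": [[35, 60]]
  },
  "code": {
    "length": 8,
    "alphabet": [1, 2, 3]
  },
  "calibration": {
    "threshold_min": 0.2,
    "threshold_max": 0.5
  }
}
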