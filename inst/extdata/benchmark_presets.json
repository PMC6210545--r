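{
  "comment": "Benchmark presets for simulate_benchmark(). Instance ratios mirror the published dataset profiles; farseeing_like is the 23:27412 profile scaled down by 11.5 (documented desk-scale factor) to 2 falls : 2384 ADL tiles, preserving the ratio.",
  "smartwatch_like": {
    "files": 7,
    "falls_total": 91,
    "adls_total": 90,
    "tagged": true,
    "noise_sd": 0.03
  },
  "notch_like": {
    "files": 7,
    "falls_total": 107,
    "adls_total": 2456,
    "tagged": false,
    "noise_sd": 0.03
  },
  "farseeing_like": {
    "files": 2,
    "falls_total": 2,
    "adls_total": 2384,
    "tagged": false,
    "noise_sd": 0.03
  }
}
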