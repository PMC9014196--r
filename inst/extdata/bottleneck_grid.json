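{
  "fst": {
    "nX": 10,
    "nY": 10,
    "grid": {
      "Dprime": [0.5, 1, 2, 5, 10, 20],
      "rate": [10, 1, 0.1],
      "size_ratio": [1, 2, 10],
      "eta_x": 10000
    },
    "bottleneck": {
      "Dprime": [0.5, 1, 2, 5, 10, 20],
      "scenarios": ["none", "recent", "postsplit", "ancestral"],
      "eta0": 10000,
      "rate": 1
    }
  }
}
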