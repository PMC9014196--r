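{
  "tree": {
    "newick": "(X:1000,Y:1000)XY;",
    "sizes": {"X": [[0, 500]], "Y": [[0, 500]], "XY": [[0, 500]]},
    "time_units": "generations"
  },
  "moments": {
    "pop_pairs": [["X", "X"], ["X", "Y"], ["Y", "Y"]],
    "joint": [
      {"pops": {"i1": "X", "i2": "X", "j1": "Y", "j2": "Y"},
       "pairA": ["i1", "i2"], "pairB": ["j1", "j2"]}
    ]
  },
  "diffstats": {"mu": [0.0005], "nX": [4], "nY": [4]},
  "simulate": {"samples": {"X": 3, "Y": 3}, "R": 1000, "seed": 1, "mu": 0.0005}
}
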