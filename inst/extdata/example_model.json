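{
  "latents": ["xi1", "xi2", "xi3", "eta1", "eta2", "eta3"],
  "blocks": {
    "xi1": ["x1", "x2", "x3", "x4"],
    "xi2": ["x5", "x6", "x7", "x8"],
    "xi3": ["x9", "x10", "x11", "x12"],
    "eta1": ["x13", "x14", "x15", "x16"],
    "eta2": ["x17", "x18", "x19", "x20"],
    "eta3": ["x21", "x22", "x23", "x24"]
  },
  "paths": [
    [
      "xi1",
      "eta1",
      "gamma11"
    ],
    [
      "xi2",
      "eta1",
      "gamma12"
    ],
    [
      "xi1",
      "eta2",
      "gamma21"
    ],
    [
      "xi2",
      "eta2",
      "gamma22"
    ],
    [
      "xi3",
      "eta2",
      "gamma23"
    ],
    [
      "eta1",
      "eta3",
      "beta31"
    ],
    [
      "eta2",
      "eta3",
      "beta32"
    ]
  ],
  "exo_correlations": {
    "xi1~~xi2": 0.4,
    "xi1~~xi3": 0,
    "xi2~~xi3": 0
  }
}
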