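{
  "schema": "cmap-rates/1",
  "note": "synthetic illustrative rate assignment (not the source publication's values): fast activation, slower recovery and feedback, giving a transient IRp+IRip response",
  "values": {
    "k1a": 10,
    "k1c": 5,
    "k1basal": 0.05,
    "k1d": 5,
    "k1g": 1,
    "k1f": 10,
    "k1r": 0.5,
    "k2a": 5,
    "k2b": 1,
    "k2c": 2,
    "k2d": 1,
    "k2f": 1,
    "k2g": 0.5,
    "k2basal": 0.05,
    "k3a": 2,
    "k3b": 0.5,
    "k4a": 2,
    "k4b": 1,
    "k4c": 2,
    "k4e": 2,
    "k4f": 1,
    "k4h": 1,
    "k5a1": 2,
    "k5a2": 2,
    "k5b": 1,
    "k5c": 2,
    "k5d": 1,
    "k6f1": 2,
    "k6f2": 2,
    "k6b": 1,
    "km6": 0.3,
    "n6": 2,
    "k7f": 2,
    "k7b": 1,
    "k9f1": 2,
    "k9b1": 1,
    "km9": 0.3,
    "n9": 2,
    "k9f2": 2,
    "k9b2": 1
  }
}
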