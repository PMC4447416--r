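{
  "schema": "cmap-rules/1",
  "rules": [
    {
      "kind": "transient_up",
      "observable": ["IRp", "IRip"],
      "delta": 0.05,
      "rho": 0.5
    },
    {
      "kind": "transient_up",
      "observable": ["IRS1p", "IRS1p307"],
      "delta": 0.05,
      "rho": 0.5
    }
  ]
}
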