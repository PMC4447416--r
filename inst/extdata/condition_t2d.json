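{
  "schema": "cmap-condition/1",
  "name": "t2d",
  "scale": {
    "IR": 0.55,
    "GLUT4": 0.5,
    "diabetes": 0.15
  },
  "clamp": {}
}
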