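{
  "root": {
    "feature": "yD",
    "threshold": -0.0293990630471561,
    "left": {
      "class": "DFG-out"
    },
    "right": {
      "feature": "yF",
      "threshold": 0.0617858269265538,
      "left": {
        "class": "DFG-in"
      },
      "right": {
        "class": "DFG-outlike"
      }
    }
  }
}
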