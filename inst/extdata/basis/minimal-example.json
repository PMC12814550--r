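{
  "name": "minimal-example",
  "comment": "Structured (JSON) basis dialect example: STO-3G parameters for H and He.",
  "elements": {
    "H": {
      "shells": {
        "l": [0],
        "exponents": [[3.42525091, 0.62391373, 0.16885540]],
        "coefficients": [[0.15432897, 0.53532814, 0.44463454]]
      }
    },
    "He": {
      "shells": {
        "l": [0],
        "exponents": [[6.36242139, 1.15892300, 0.31364979]],
        "coefficients": [[0.15432897, 0.53532814, 0.44463454]]
      }
    }
  }
}
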