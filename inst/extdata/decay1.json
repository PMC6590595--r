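{
  "species": [
    "X"
  ],
  "reactions": [
    {
      "reactants": {
        "X": 1
      },
      "products": {},
      "rate_param": "k_deg"
    }
  ],
  "parameters": {
    "k_deg": 2
  },
  "inputs": {
    "u": "X"
  },
  "readouts": [
    "X"
  ]
}
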