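{
  "species": [
    "A",
    "B",
    "C"
  ],
  "reactions": [
    {
      "reactants": {
        "A": 1,
        "B": 1
      },
      "products": {
        "C": 1
      },
      "rate_param": "k_bind"
    },
    {
      "reactants": {
        "A": 1
      },
      "products": {},
      "rate_param": "k_degA"
    },
    {
      "reactants": {
        "B": 1
      },
      "products": {},
      "rate_param": "k_degB"
    },
    {
      "reactants": {
        "C": 1
      },
      "products": {},
      "rate_param": "k_degC"
    }
  ],
  "parameters": {
    "k_bind": 1,
    "k_degA": 1,
    "k_degB": 1,
    "k_degC": 1
  },
  "inputs": {
    "uA": "A",
    "uB": "B"
  },
  "readouts": [
    "C"
  ]
}
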