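[
  {
    "name": "lexan",
    "density": 1.20,
    "I": 73.1,
    "composition": {"C": 0.75575, "O": 0.18876, "H": 0.05549}
  },
  {
    "name": "solid_water",
    "density": 1.044,
    "I": 67.0,
    "composition": {"C": 0.6717, "O": 0.1988, "H": 0.0809,
                    "N": 0.0241, "Ca": 0.0231, "Cl": 0.0014}
  }
]
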