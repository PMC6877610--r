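{
  "name": "nav15_hh_row_b",
  "family": "hh",
  "gbar": 0.1,
  "E_rev": 65,
  "temperature": {
    "T": 24,
    "T_base": 6.3,
    "q10_base": 3
  },
  "gates": [
    {
      "name": "m",
      "exponent": 3,
      "alpha": {
        "form": "linoid",
        "params": {
          "A": 0.03,
          "V12": -40,
          "k": 10
        }
      },
      "beta": {
        "form": "exponential",
        "params": {
          "A": 0.3,
          "V12": -65,
          "k": -18
        }
      }
    },
    {
      "name": "h",
      "exponent": 1,
      "alpha": {
        "form": "exponential",
        "params": {
          "A": 0.002,
          "V12": -65,
          "k": -10
        }
      },
      "beta": {
        "form": "sigmoid",
        "params": {
          "A": 0.5,
          "V12": -25,
          "k": -15
        }
      }
    }
  ]
}
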