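{
  "name": "nav15_markov",
  "family": "markov",
  "gbar": 0.1,
  "E_rev": 65,
  "temperature": {
    "T": 24,
    "T_base": 20,
    "q10_base": 3
  },
  "states": ["C1", "C2", "O1", "I1", "I2"],
  "open_state": "O1",
  "transitions": [
    {
      "from": "C1",
      "to": "C2",
      "rate": {
        "form": "double_sigmoid",
        "params": {
          "B_dep": 8,
          "V_dep": -16,
          "k_dep": -9
        }
      }
    },
    {
      "from": "C2",
      "to": "C1",
      "rate": {
        "form": "double_sigmoid",
        "params": {
          "B_hyp": 2,
          "V_hyp": -82,
          "k_hyp": 5,
          "B_dep": 8,
          "V_dep": -16,
          "k_dep": -9
        }
      }
    },
    {
      "from": "C2",
      "to": "O1",
      "rate": {
        "form": "double_sigmoid",
        "params": {
          "B_dep": 8,
          "V_dep": -26,
          "k_dep": -9
        }
      }
    },
    {
      "from": "O1",
      "to": "C2",
      "rate": {
        "form": "double_sigmoid",
        "params": {
          "B_hyp": 3,
          "V_hyp": -92,
          "k_hyp": 5,
          "B_dep": 8,
          "V_dep": -26,
          "k_dep": -9
        }
      }
    },
    {
      "from": "O1",
      "to": "I1",
      "rate": {
        "form": "double_sigmoid",
        "params": {
          "B_hyp": 8,
          "V_hyp": -50,
          "k_hyp": 4,
          "B_dep": 6,
          "V_dep": 10,
          "k_dep": -100
        }
      }
    },
    {
      "from": "I1",
      "to": "O1",
      "rate": {
        "form": "double_sigmoid",
        "params": {
          "B_hyp": 1e-05,
          "V_hyp": -20,
          "k_hyp": 10
        }
      }
    },
    {
      "from": "I1",
      "to": "C1",
      "rate": {
        "form": "double_sigmoid",
        "params": {
          "B_hyp": 0.35,
          "V_hyp": -122,
          "k_hyp": 9
        }
      }
    },
    {
      "from": "C1",
      "to": "I1",
      "rate": {
        "form": "double_sigmoid",
        "params": {
          "B_dep": 0.04,
          "V_dep": -78,
          "k_dep": -10
        }
      }
    },
    {
      "from": "I1",
      "to": "I2",
      "rate": {
        "form": "double_sigmoid",
        "params": {
          "B_dep": 0.00018,
          "V_dep": -60,
          "k_dep": -5
        }
      }
    },
    {
      "from": "I2",
      "to": "I1",
      "rate": {
        "form": "double_sigmoid",
        "params": {
          "B_hyp": 0.001825,
          "V_hyp": -88,
          "k_hyp": 31
        }
      }
    }
  ]
}
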