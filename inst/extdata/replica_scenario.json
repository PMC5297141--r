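{
  "operators": [
    {
      "id": "A",
      "n_cases": 47,
      "phases": {
        "n_attempts": [21, 30, 13, 20],
        "p_fail": [0.35, 0.02, 0.5, 0.02]
      }
    },
    {
      "id": "B",
      "n_cases": 50,
      "phases": {
        "n_attempts": [22, 32, 14, 21],
        "p_fail": [0.35, 0.02, 0.5, 0.02]
      }
    },
    {
      "id": "C",
      "n_cases": 34,
      "phases": {
        "n_attempts": [12, 18, 8, 11],
        "p_fail": [0.35, 0.02, 0.5, 0.02]
      }
    }
  ],
  "covariates": {
    "attending_assist": {
      "prevalence": 0.35,
      "effect": -1.5
    },
    "cytopathologist": {
      "prevalence": 0.5,
      "effect": 0
    },
    "midazolam": {
      "shape": 8,
      "scale": 1,
      "unit": 0.5,
      "threshold": 10,
      "effect": 0
    },
    "fentanyl": {
      "shape": 7,
      "scale": 20,
      "unit": 25,
      "threshold": 300,
      "effect": 0
    }
  },
  "nodes_per_case": {
    "1": 0.45,
    "2": 0.45,
    "3": 0.1
  },
  "seed": 20080301
}
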