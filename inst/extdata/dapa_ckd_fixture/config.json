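{
  "states": [
    {
      "id": "ckd1",
      "label": "CKD stage 1",
      "egfr_band": ">90 ml/min per 1.73 m^2",
      "category": "ckd_stage_1",
      "absorbing": false,
      "drug_cost_applies": true
    },
    {
      "id": "ckd2",
      "label": "CKD stage 2",
      "egfr_band": "60-89 ml/min per 1.73 m^2",
      "category": "ckd_stage_2",
      "absorbing": false,
      "drug_cost_applies": true
    },
    {
      "id": "ckd3a",
      "label": "CKD stage 3a",
      "egfr_band": "45-59 ml/min per 1.73 m^2",
      "category": "ckd_stage_3a",
      "absorbing": false,
      "drug_cost_applies": true
    },
    {
      "id": "ckd3b",
      "label": "CKD stage 3b",
      "egfr_band": "30-44 ml/min per 1.73 m^2",
      "category": "ckd_stage_3b",
      "absorbing": false,
      "drug_cost_applies": true
    },
    {
      "id": "ckd4",
      "label": "CKD stage 4",
      "egfr_band": "15-29 ml/min per 1.73 m^2",
      "category": "ckd_stage_4",
      "absorbing": false,
      "drug_cost_applies": true
    },
    {
      "id": "ckd5",
      "label": "CKD stage 5 (pre-RRT)",
      "egfr_band": "<15 ml/min per 1.73 m^2",
      "category": "ckd_stage_5",
      "absorbing": false,
      "drug_cost_applies": true
    },
    {
      "id": "dialysis",
      "label": "Dialysis",
      "category": "dialysis",
      "absorbing": false,
      "drug_cost_applies": false
    },
    {
      "id": "tx_init",
      "label": "Transplant (initial cycle)",
      "category": "transplant_initial",
      "absorbing": false,
      "drug_cost_applies": false
    },
    {
      "id": "tx_maint",
      "label": "Transplant (maintenance)",
      "category": "transplant_maintenance",
      "absorbing": false,
      "drug_cost_applies": false
    },
    {
      "id": "dead",
      "label": "Dead",
      "category": "dead",
      "absorbing": true,
      "drug_cost_applies": false
    }
  ],
  "costs": {
    "drug_annual": {
      "dapagliflozin": {
        "mean": 463.55,
        "se": 0.01
      },
      "soc": {
        "mean": 46.32,
        "se": 0.01
      }
    },
    "state_mgmt_annual": {
      "ckd1": {
        "mean": 343.91,
        "se": 46
      },
      "ckd2": {
        "mean": 484.07,
        "se": 29.52
      },
      "ckd3a": {
        "mean": 425.63,
        "se": 54.45
      },
      "ckd3b": {
        "mean": 1287.52,
        "se": 82.39
      },
      "ckd4": {
        "mean": 1726.12,
        "se": 27.84
      },
      "ckd5": {
        "mean": 3194.31,
        "se": 11909.6
      }
    },
    "dialysis_annual": {
      "mean": 44731.4,
      "se": 1118.29
    },
    "transplant_initial_once": {
      "mean": 117805.11,
      "se": 1982.69
    },
    "transplant_maint_annual": {
      "mean": 25281.64,
      "se": 632.04
    },
    "ae_unit_cost": {
      "volume_depletion": {
        "mean": 1330.9,
        "se": 350.32
      },
      "severe_hypoglycaemia": {
        "mean": 8802.57,
        "se": 462.78
      },
      "fracture": {
        "mean": 7862.22,
        "se": 391.31
      },
      "diabetic_ketoacidosis": {
        "mean": 8802.57,
        "se": 462.78
      },
      "amputation": {
        "mean": 6868.35,
        "se": 459.94
      }
    }
  },
  "utilities": {
    "state_utility": {
      "ckd1": {
        "mean": 0.93,
        "se": 0.005
      },
      "ckd2": {
        "mean": 0.87,
        "se": 0.005
      },
      "ckd3a": {
        "mean": 0.88,
        "se": 0.002
      },
      "ckd3b": {
        "mean": 0.88,
        "se": 0.002
      },
      "ckd4": {
        "mean": 0.87,
        "se": 0.003
      },
      "ckd5": {
        "mean": 0.85,
        "se": 0.009
      },
      "dialysis": {
        "mean": 0.85,
        "se": 0.17
      },
      "tx_init": {
        "mean": 0.95,
        "se": 0.05
      },
      "tx_maint": {
        "mean": 0.95,
        "se": 0.05
      }
    },
    "ae_decrement": {
      "volume_depletion": {
        "mean": 0.05,
        "se": 0.01
      },
      "severe_hypoglycaemia": {
        "mean": 0.19,
        "se": 0
      },
      "fracture": {
        "mean": 0.072,
        "se": 0.031
      },
      "diabetic_ketoacidosis": {
        "mean": 0.01,
        "se": 0.01
      },
      "amputation": {
        "mean": 0.266,
        "se": 0.05
      }
    }
  },
  "adverse_events": [
    {
      "name": "volume_depletion",
      "rate_per_cycle": {
        "dapagliflozin": 0.002,
        "soc": 0.0014
      },
      "duration_cycles": 1
    },
    {
      "name": "severe_hypoglycaemia",
      "rate_per_cycle": {
        "dapagliflozin": 0.0011,
        "soc": 0.0022
      },
      "duration_cycles": 1
    },
    {
      "name": "fracture",
      "rate_per_cycle": {
        "dapagliflozin": 0.0014,
        "soc": 0.0011
      },
      "duration_cycles": 1
    },
    {
      "name": "diabetic_ketoacidosis",
      "rate_per_cycle": {
        "dapagliflozin": 2e-05,
        "soc": 7e-05
      },
      "duration_cycles": 1
    },
    {
      "name": "amputation",
      "rate_per_cycle": {
        "dapagliflozin": 0.00055,
        "soc": 0.0006
      },
      "duration_cycles": 1
    }
  ],
  "econ": {
    "annual_discount": 0.03,
    "cycle_length_months": 1,
    "wtp_per_qaly": 46000,
    "fx_rm_per_usd": 4.14,
    "horizon_cycles": 480,
    "discontinuation_rate_per_cycle": 0.004
  },
  "init_dist": {
    "ckd1": 0,
    "ckd2": 0.11,
    "ckd3a": 0.31,
    "ckd3b": 0.33,
    "ckd4": 0.25,
    "ckd5": 0,
    "dialysis": 0,
    "tx_init": 0,
    "tx_maint": 0,
    "dead": 0
  }
}
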