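{
  "command": "simulate",
  "tool": "pedasthma",
  "version": "1.0.0",
  "timestamp": "2026-09-20T03:30:49+0000",
  "reference_date": "2015-06-30",
  "seed": 2024,
  "inputs": {},
  "outputs": {
    "inst/extdata/synthetic_demo/patient.csv": "42d6aa1ecc8af3c93de6a1be2513cda4",
    "inst/extdata/synthetic_demo/billing.csv": "9f10188cedba4e0c08631762775705eb",
    "inst/extdata/synthetic_demo/encounter_diagnosis.csv": "f36a0b25a3ad73e698c2e0d3e6b77ce5",
    "inst/extdata/synthetic_demo/health_condition.csv": "dc9e4572788ae4a565d55f8d75df4e75",
    "inst/extdata/synthetic_demo/medication.csv": "3b8fb449caab86d6efad38e720b2e75e",
    "inst/extdata/synthetic_demo/gold.csv": "8edc681e267579b19838d3d51ef0491a",
    "inst/extdata/synthetic_demo/cohort_config.yaml": "1eb14711e4333b845881d70ff3f53f26"
  },
  "config": {
    "n_patients": 30,
    "prevalence": 0.143,
    "age_low": 1,
    "age_high": 17,
    "seed": 2024,
    "case_profile": {
      "p_billing": 0.5,
      "p_encounter": 0.75,
      "p_condition": 0.5,
      "p_text_given_row": 0.7,
      "rx_dist": [0.06, 0.14, 0.4, 0.25, 0.15]
    },
    "control_profile": {
      "p_excluded_text": 0.05,
      "p_benign_text": 0.15,
      "p_code": 0.004,
      "rx_dist": [0.9, 0.09, 0.01]
    },
    "target_sensitivity": {},
    "target_specificity": {},
    "suspected_rate": 0.06,
    "reference_date": "2015-06-30"
  }
}
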