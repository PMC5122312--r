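n_patients: 30
prevalence: 0.143
age_low: 1
age_high: 17
seed: 2024
case_profile:
  p_billing: 0.5
  p_encounter: 0.75
  p_condition: 0.5
  p_text_given_row: 0.7
  rx_dist:
    '0': 0.06
    '1': 0.14
    '2': 0.4
    '3': 0.25
    '4': 0.15
control_profile:
  p_excluded_text: 0.05
  p_benign_text: 0.15
  p_code: 0.004
  rx_dist:
    '0': 0.9
    '1': 0.09
    '2': 0.01
target_sensitivity: ~
target_specificity: ~
suspected_rate: 0.06
reference_date: '2015-06-30'
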