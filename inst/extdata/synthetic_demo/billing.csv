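"patient_id","date","diagnosis_code"
"P000009","2014-01-25","493"
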