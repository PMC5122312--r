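"patient_id","date_onset","condition_code","condition_text"
"P000009","2012-11-01","493.9",""
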