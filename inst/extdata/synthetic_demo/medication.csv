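"patient_id","date","drug_name","atc_code"
"P000009","2013-11-16","Triamcinolone","R03BA06"
"P000009","2014-11-22","Montelukast","R03DC03"
"P000011","2014-01-19","Formoterol and beclometasone 100mcg inhaler",""
"P000011","2014-11-14","Dexamethasone","H02AB02"
"P000012","2013-02-01","Budesonide","R03BA02"
"P000012","2013-11-14","Formoterol and budesonide","R03AK07"
"P000012","2014-11-23","Salmeterol and fluticasone 100mcg inhaler",""
"P000018","2013-07-10","Salmeterol and fluticasone","R03AK06"
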