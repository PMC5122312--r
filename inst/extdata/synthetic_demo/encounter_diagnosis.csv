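"patient_id","date","diagnosis_code","diagnosis_text"
"P000005","2014-03-20","","gastroesophageal reflux"
"P000008","2013-03-30","","gastroesophageal reflux"
"P000010","2015-02-11","","asthma?"
"P000011","2014-03-19","","asthma"
"P000012","2012-11-20","","Asthma, mild intermittent"
"P000014","2014-01-15","","croup"
"P000015","2013-10-18","","URTI"
"P000018","2015-04-01","","allergic asthma"
"P000019","2015-01-05","","otitis media"
"P000022","2014-06-10","","query asthma"
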