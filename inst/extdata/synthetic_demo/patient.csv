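"patient_id","birth_date","sex"
"P000001","2001-06-06","M"
"P000002","1997-12-13","M"
"P000003","1999-01-28","M"
"P000004","2004-06-23","F"
"P000005","2004-12-26","M"
"P000006","2010-08-19","F"
"P000007","2008-04-15","M"
"P000008","1998-08-09","F"
"P000009","2012-04-27","F"
"P000010","2012-07-16","F"
"P000011","1997-08-21","F"
"P000012","1998-05-21","M"
"P000013","2011-10-09","F"
"P000014","2014-03-20","M"
"P000015","2009-01-23","F"
"P000016","2006-01-29","F"
"P000017","2000-01-22","F"
"P000018","2001-10-09","M"
"P000019","1998-08-03","F"
"P000020","2003-11-02","M"
"P000021","2013-03-08","F"
"P000022","1998-05-03","M"
"P000023","2003-05-10","F"
"P000024","2009-08-30","M"
"P000025","1998-11-18","F"
"P000026","2009-05-11","M"
"P000027","2011-12-17","F"
"P000028","2013-11-19","M"
"P000029","2004-02-26","F"
"P000030","2006-01-07","F"
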