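"patient_id","gold_case"
"P000001",0
"P000002",0
"P000003",0
"P000004",0
"P000005",0
"P000006",0
"P000007",0
"P000008",0
"P000009",1
"P000010",0
"P000011",1
"P000012",1
"P000013",0
"P000014",0
"P000015",0
"P000016",0
"P000017",0
"P000018",1
"P000019",0
"P000020",0
"P000021",0
"P000022",0
"P000023",0
"P000024",0
"P000025",0
"P000026",0
"P000027",0
"P000028",0
"P000029",0
"P000030",0
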