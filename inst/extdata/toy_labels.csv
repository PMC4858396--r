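"compound_id","liver_damage"
"CMPD00001",0
"CMPD00002",1
"CMPD00003",0
"CMPD00004",1
"CMPD00005",0
"CMPD00006",0
"CMPD00007",0
"CMPD00008",0
"CMPD00009",1
"CMPD00010",0
"CMPD00011",1
"CMPD00012",0
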