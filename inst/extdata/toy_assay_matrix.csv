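"compound_id","AID0001","AID0002","AID0003","AID0004"
"CMPD00001",,0,0,0
"CMPD00002",1,1,0,0
"CMPD00003",0,,,0
"CMPD00004",1,1,0,0
"CMPD00005",0,0,0,0
"CMPD00006",1,0,0,
"CMPD00007",0,0,0,0
"CMPD00008",0,0,0,0
"CMPD00009",,0,0,0
"CMPD00010",0,,,
"CMPD00011",1,1,,
"CMPD00012",1,,0,0
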