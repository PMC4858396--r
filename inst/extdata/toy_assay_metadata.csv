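"assay_id","relevant","in_vitro","description"
"AID0001",TRUE,TRUE,"planted liver-associated qHTS assay"
"AID0002",TRUE,TRUE,"planted liver-associated qHTS assay"
"AID0003",FALSE,TRUE,"independent background assay"
"AID0004",FALSE,TRUE,"independent background assay"
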