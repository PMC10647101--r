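figo_stage,histology,lvsi,level
IA,endometrioid_low_grade,negative;focal,low
,non_endometrioid,,high
III;IV,,,high
,,substantial,high_intermediate
II,,,high_intermediate
IB,endometrioid_high_grade,,high_intermediate
IB,endometrioid_low_grade,,intermediate
IA,endometrioid_high_grade,,intermediate
,,,high_intermediate
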