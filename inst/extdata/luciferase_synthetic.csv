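sample_id,tissue,treatment,firefly_rlu,renilla_rlu
L1,liver,vehicle,1180,142
L2,liver,vehicle,947,118
L3,liver,vehicle,1065,131
L4,liver,agonist,8630,155
L5,liver,agonist,7815,129
L6,liver,agonist,9120,147
R1,retina,vehicle,312,104
R2,retina,vehicle,287,96
R3,retina,vehicle,334,112
R4,retina,agonist,301,99
R5,retina,agonist,356,121
R6,retina,agonist,322,108
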