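sample_id,group,gene,ct
r1,vehicle,Acox1,24.82
r1,vehicle,Acox1,24.78
r1,vehicle,GAPDH,19.41
r1,vehicle,GAPDH,19.39
r2,vehicle,Acox1,25.11
r2,vehicle,Acox1,25.09
r2,vehicle,GAPDH,19.72
r2,vehicle,GAPDH,19.68
r3,vehicle,Acox1,24.95
r3,vehicle,Acox1,25.05
r3,vehicle,GAPDH,19.55
r3,vehicle,GAPDH,19.45
t1,agonist,Acox1,22.31
t1,agonist,Acox1,22.29
t1,agonist,GAPDH,19.50
t1,agonist,GAPDH,19.52
t2,agonist,Acox1,22.64
t2,agonist,Acox1,22.56
t2,agonist,GAPDH,19.61
t2,agonist,GAPDH,19.59
t3,agonist,Acox1,22.47
t3,agonist,Acox1,22.55
t3,agonist,GAPDH,19.38
t3,agonist,GAPDH,19.42
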