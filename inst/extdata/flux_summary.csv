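zone,species,avg_o3_ambient_ppb,pod0_ambient_mmol_m2,avg_o3_cl_ppb,pod0_cl_mmol_m2
ATE,Pinus mugo,52.7,10.9,158.5,32.8
ATE,Pinus cembra,52.7,12.8,174.6,42.5
FH,Pinus mugo,27.5,8.2,116.0,32.2
FH,Pinus cembra,27.5,9.9,141.1,47.4
FH,Pinus sylvestris,27.5,9.9,137.8,39.4
FH,Picea abies,27.5,15.0,124.1,62.4
FH,Abies alba,27.5,15.0,165.3,83.2
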