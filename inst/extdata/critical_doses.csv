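zone,species,sum_o3_oxs_ppm
ATE,Pinus mugo,464.0
ATE,Pinus cembra,511.3
FH,Pinus mugo,426.0
FH,Pinus cembra,518.2
FH,Pinus sylvestris,506.1
FH,Picea abies,455.8
FH,Abies alba,606.8
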