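zone,species,series_index,oxs
ATE,Pinus mugo,1,-0.01
ATE,Pinus mugo,2,-0.03
ATE,Pinus mugo,3,-0.06
ATE,Pinus mugo,4,-0.12
ATE,Pinus mugo,5,-0.24
ATE,Pinus mugo,6,-0.32
ATE,Pinus cembra,1,-0.01
ATE,Pinus cembra,2,-0.02
ATE,Pinus cembra,3,-0.09
ATE,Pinus cembra,4,-0.10
ATE,Pinus cembra,5,-0.18
ATE,Pinus cembra,6,-0.28
FH,Pinus mugo,1,-0.01
FH,Pinus mugo,2,-0.04
FH,Pinus mugo,3,-0.06
FH,Pinus mugo,4,-0.12
FH,Pinus mugo,5,-0.30
FH,Pinus mugo,6,-0.39
FH,Pinus cembra,1,-0.02
FH,Pinus cembra,2,-0.03
FH,Pinus cembra,3,-0.02
FH,Pinus cembra,4,-0.12
FH,Pinus cembra,5,-0.17
FH,Pinus cembra,6,-0.29
FH,Pinus sylvestris,1,0.00
FH,Pinus sylvestris,2,-0.03
FH,Pinus sylvestris,3,-0.05
FH,Pinus sylvestris,4,-0.12
FH,Pinus sylvestris,5,-0.14
FH,Pinus sylvestris,6,-0.28
FH,Picea abies,1,-0.02
FH,Picea abies,2,-0.02
FH,Picea abies,3,-0.08
FH,Picea abies,4,-0.10
FH,Picea abies,5,-0.13
FH,Picea abies,6,-0.30
FH,Abies alba,1,0.00
FH,Abies alba,2,-0.02
FH,Abies alba,3,-0.06
FH,Abies alba,4,-0.11
FH,Abies alba,5,-0.09
FH,Abies alba,6,-0.22
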