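zone,species,series_index,inx_pct
ATE,Pinus mugo,0,11.0
ATE,Pinus mugo,1,12.7
ATE,Pinus mugo,2,14.3
ATE,Pinus mugo,3,17.1
ATE,Pinus mugo,4,23.7
ATE,Pinus mugo,5,34.9
ATE,Pinus mugo,6,43.2
ATE,Pinus cembra,0,14.8
ATE,Pinus cembra,1,16.4
ATE,Pinus cembra,2,16.6
ATE,Pinus cembra,3,24.4
ATE,Pinus cembra,4,25.0
ATE,Pinus cembra,5,33.4
ATE,Pinus cembra,6,42.8
FH,Pinus mugo,0,9.3
FH,Pinus mugo,1,10.1
FH,Pinus mugo,2,13.2
FH,Pinus mugo,3,14.9
FH,Pinus mugo,4,21.5
FH,Pinus mugo,5,38.9
FH,Pinus mugo,6,48.4
FH,Pinus cembra,0,9.1
FH,Pinus cembra,1,10.7
FH,Pinus cembra,2,11.8
FH,Pinus cembra,3,11.5
FH,Pinus cembra,4,21.3
FH,Pinus cembra,5,25.6
FH,Pinus cembra,6,38.3
FH,Pinus sylvestris,0,12.1
FH,Pinus sylvestris,1,12.4
FH,Pinus sylvestris,2,15.4
FH,Pinus sylvestris,3,17.5
FH,Pinus sylvestris,4,24.0
FH,Pinus sylvestris,5,25.8
FH,Pinus sylvestris,6,40.4
FH,Abies alba,0,10.0
FH,Abies alba,1,10.0
FH,Abies alba,2,11.9
FH,Abies alba,3,16.0
FH,Abies alba,4,20.9
FH,Abies alba,5,19.2
FH,Abies alba,6,32.0
FH,Picea abies,0,28.6
FH,Picea abies,1,31.0
FH,Picea abies,2,30.9
FH,Picea abies,3,36.6
FH,Picea abies,4,38.4
FH,Picea abies,5,41.5
FH,Picea abies,6,58.4
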