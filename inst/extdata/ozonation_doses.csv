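zone,series_index,exposure_h,sum_o3_ppm
ATE,1,0,154
ATE,2,1,323
ATE,3,3,668
ATE,4,5,991
ATE,5,7,1312
ATE,6,10,1825
FH,1,0,101
FH,2,1,267
FH,3,3,600
FH,4,5,932
FH,5,7,1265
FH,6,10,1764
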