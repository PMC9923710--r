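lo_kg,hi_kg,dose_mg
120,Inf,3000
90,120,2700
60,90,2400
40,60,2100
30,40,1800
20,30,1500
10,20,1200
5,10,900
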