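lo_kg,hi_kg,day1_mg,day15_mg
120,Inf,2400,1200
90,120,2100,1200
60,90,1800,1200
40,60,1500,1200
30,40,900,900
20,30,600,600
10,20,600,300
5,10,300,300
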