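lo_kg,hi_kg,week1_mg,week2_mg,week3_mg,week4_mg,week5_mg,maintenance_interval_days
40,Inf,900,900,900,900,1200,14
30,40,600,600,900,,900,14
20,30,600,600,600,,600,14
10,20,600,300,,300,,14
5,10,300,300,,,300,21
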