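patient,age_years,sex,duration_years,diagnosis,baseline_seizures_per_month,reduction_pct,responsiveness
1,35,M,29,CLE,90,88,Responder
2,38,F,20,Rt. FLE,1,100,Responder
3,37,M,28,Rt. FPLE,11,-24,Nonresponder
4,55,M,29,Lt. TLE,2,61,Responder
5,21,M,12,IGE,4,69,Responder
6,31,M,10,Both TLE,1.5,-33,Nonresponder
7,37,M,7,Both FTLE,2.5,-7,Nonresponder
8,35,F,26,Lt. FPLE,10,-73,Nonresponder
9,23,M,12,IGE,14,33,Nonresponder
10,35,M,15,Both FLE,35,53,Responder
11,41,M,28,Rt. PLE,3,100,Responder
12,25,M,16,IGE,45,-58,Nonresponder
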