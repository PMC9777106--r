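population,strategy,months_l1,months_l2,months_total,qaly,cost_eur
BRAF-m,Anti-PD1 -> Bi-TT,15.6,32.3,47.9,3.2,502045
BRAF-m,Bi-TT -> Anti-PD1,21.4,17.0,38.4,2.4,446766
BRAF-m,IPI+NIVO -> Bi-TT,9.7,25.7,35.4,2.0,558168
BRAF-m,MONO-TT -> Bi-TT,12.1,29.4,41.5,2.4,435702
BRAF-m,MONO-TT -> Anti-PD1,21.4,18.9,40.3,2.5,375736
BRAF-wt,Anti-PD1,14.7,8.0,22.7,1.3,178726
BRAF-wt,IPI+NIVO,21.3,5.3,26.6,1.6,351590
BRAF-wt,Ipilimumab,5.6,18.5,24.1,1.4,190322
BRAF-wt,Chemotherapy,4.1,16.3,20.4,1.1,151475
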