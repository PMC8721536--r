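activity_id,gene_id,alias,km_mM,sodium_dependent,vmax_literature_nmol_h,mechanism
B0AT2,SLC6A15,B0AT2,0.160,TRUE,NA,symporter
LAT1,SLC7A5,LAT1,0.032,FALSE,0.162,antiporter
b0+AT,SLC7A9,"b0,+AT",1.1,FALSE,NA,antiporter
y+LAT1,SLC7A7,y+LAT1,0.0317,TRUE,0.38,antiporter
y+LAT2,SLC7A6,y+LAT2,0.236,TRUE,1.60,antiporter
ASCT2,SLC1A5,ASCT2,0.367,TRUE,1.01,antiporter
LAT4_high,SLC43A2,LAT4_high,0.103,FALSE,0.024,uniporter
LAT4_low,SLC43A2,LAT4_low,3.73,FALSE,3.52,uniporter
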