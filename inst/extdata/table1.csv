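id,group,rmssd_urban_mean,rmssd_urban_sd,rmssd_urban_lo,rmssd_urban_hi,rmssd_green_mean,rmssd_green_sd,rmssd_green_lo,rmssd_green_hi,sdnn_urban_mean,sdnn_urban_sd,sdnn_urban_lo,sdnn_urban_hi,sdnn_green_mean,sdnn_green_sd,sdnn_green_lo,sdnn_green_hi,delta_rmssd,sig_rmssd,delta_sdnn,sig_sdnn,cortisol_pct_urban,cortisol_pct_green
GR2,1,33,4,25,39,117,41,60,167,50,4,42,56,108,17,74,126,83,**,57,**,-18.8,-46.6
GR3,1,21,11,11,48,22,10,14,47,37,10,24,50,41,6,35,53,1.7,**,3.93,*,-24.7,-47.9
GR5,1,41,29,16,112,56,41,15,143,49,23,27,101,62,34,30,135,15,**,14,**,-58.2,-59.2
GR14,1,36,15,15,55,39,10,29,65,58,17,35,79,60,6,55,78,2.97,,2.58,,-25.8,-70.9
GR15,1,40,15,24,70,57,12,33,71,61,20,43,106,67,9,48,78,17,**,7,,-28.9,-67.9
GR16,1,22,11,13,49,30,8,20,41,45,14,29,69,53,14,36,78,8,**,8,**,-59.3,-59.9
GR17,1,45,12,34,76,165,66,13,235,72,9,64,93,168,57,13,227,120,**,96,**,-10.0,-42.7
GR18,1,19,5,14,29,37,12,15,51,35,7,28,50,43,9,26,53,18,**,7,**,-50.4,-46.7
GR20,1,19,4,15,28,20,11,10,46,35,4,30,44,40,11,30,67,0.22,,4,,-41.2,-60.1
GR1,2,129,13,113,158,77,25,36,106,120,13,110,153,85,17,55,106,-52,**,-34,**,-19.5,-47.4
GR6,2,72,30,44,140,56,24,33,108,82,20,58,113,73,16,59,110,-16,**,-9,**,-46.4,-68.4
GR7,2,88,16,64,110,61,11,43,75,87,17,61,110,66,13,45,83,-27,**,-21,**,-43.7,-21.2
GR8,2,108,42,61,185,63,22,30,90,122,39,77,189,86,17,63,106,-46,**,-37,**,-50.5,-58.1
GR11,2,50,32,24,134,25,9,12,35,62,30,38,142,33,4,27,39,-26,*,-30,**,-29.6,-49.7
GR13,2,42,5,36,53,14,9,4,34,44,2,42,50,25,7,18,39,-28,**,-19,**,-40.6,-47.4
GR10,3,49,11,32,62,52,10,35,63,71,18,49,101,69,3,65,74,3,,-2,,-44.6,-71.4
GR19,3,83,34,52,169,80,22,61,136,106,24,82,162,108,17,92,145,-2,,2,,-31.6,-35.4
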