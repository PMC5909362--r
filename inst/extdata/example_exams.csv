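exam_id,combination,kvp,mas,thickness_cm,device_id,age_years,glandularity_pct,hvl_mmal
p01,Mo-Mo,25,32,2,senographe-ds,61,100,0.30
p02,Mo-Mo,26,36,3,senographe-ds,55,72,0.30
p03,Mo-Mo,27,18,2.4,senographe-ds,43,91,0.31
p04,Mo-Rh,26,43,3,senographe-ds,60,72,0.42
p05,Mo-Rh,27,50,4,senographe-ds,48,65,0.43
p06,Mo-Rh,28,54,4,senographe-ds,51,50,0.44
p07,Rh-Rh,28,48,5,senographe-ds,63,33,0.45
p08,Rh-Rh,29,58,5,senographe-ds,59,33,0.47
p09,Rh-Rh,29,73,6,senographe-ds,45,35,0.47
p10,Rh-Rh,30,63,6,senographe-ds,57,21,0.48
p11,Rh-Rh,30,75,7,senographe-ds,60,12,0.48
p12,W-Rh,28,72,4.5,selenia-dimensions,55,42,0.54
p13,W-Rh,29,95,5,selenia-dimensions,43,49,0.54
p14,W-Rh,30,99,5.5,selenia-dimensions,46,42,0.56
p15,W-Rh,29,89,5,selenia-dimensions,46,49,0.54
p16,W-Rh,28,103,4,selenia-dimensions,42,65,0.54
p17,W-Ag,30,114,7,selenia-dimensions,52,12,0.62
p18,W-Ag,30,68,7,selenia-dimensions,47,24,0.62
p19,W-Ag,30,77,7,selenia-dimensions,40,24,0.62
p20,W-Ag,30,105,7,selenia-dimensions,52,12,0.62
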