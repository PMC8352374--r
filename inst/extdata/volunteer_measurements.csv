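volunteer,age_years,bmi_kg_m2,height_cm,weight_kg,tilt_steep_deg,tilt_shallow_deg,gelpad_steep_mm,gelpad_shallow_mm,bowing_steep_mm,bowing_shallow_mm
1,28,20.2,165,55,23,17,10.2,9.8,10.4,11.7
2,44,26.4,165,72,19,12,NA,NA,NA,NA
3,29,23.5,170,68,17,8,9.8,9.8,8.6,9.4
4,27,23.8,160,61,24,13,9.7,9.3,10.9,10.9
5,36,20.9,168,59,29,16,NA,10.0,NA,7.8
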