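patient,age_years,weight_kg,treatment_angle_deg,gelpad_mm,gelpad_sd_mm,nominal_gelpad_mm,bowing_mm,bowing_sd_mm
P1,64,42,6,5.3,0.5,40,4.1,0.2
P2,53,76,33,10.9,0.6,15,10.0,0.5
P3,72,57,16,8.6,0.4,15,9.0,0.5
P4,74,61,9,12.3,0.4,15,5.0,0.2
P5,59,61,24,8.0,0.4,15,10.0,0.1
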