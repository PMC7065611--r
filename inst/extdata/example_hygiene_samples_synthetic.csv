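location,surface_area_cm2,atp_rlu_cm2,atp_rlu_surface,tpc_cfu_cm2,s_aureus,enterococci,gram_negatives
Chair armrest,50,1.9,95,,,,
Chair armrest,50,0.2,10,,,,
Chair armrest,50,,,85,0,0,0
Toilet door lock,37,,,191,1,0,0
Toilet door lock,37,,,51,1,1,0
Common area table,100,0.4,40,0.5,0,0,0
Common area table,100,3.9,390,29,0,1,0
Toilet door handle,24,1.4,33.6,7.0,1,0,0
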