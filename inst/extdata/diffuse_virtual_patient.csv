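patient_id,t_days,modality,radius_mm
VPDIF,0,T1Gd,12
VPDIF,0,T2,33.04
VPDIF,60,T1Gd,17.17
VPDIF,60,T2,37.89
VPDIF,120,T1Gd,22.31
VPDIF,120,T2,42.81
VPDIF,180,T1Gd,27.44
VPDIF,180,T2,47.76
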