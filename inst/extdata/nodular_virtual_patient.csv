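patient_id,t_days,modality,radius_mm
VPNOD,0,T1Gd,12
VPNOD,0,T2,15.11
VPNOD,60,T1Gd,15.23
VPNOD,60,T2,18.34
VPNOD,120,T1Gd,18.49
VPNOD,120,T2,21.6
VPNOD,180,T1Gd,21.76
VPNOD,180,T2,24.87
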