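roi,network
mPFC,DMN
PCC,DMN
L_AI,SN
R_AI,SN
dACC,SN
L_NAcc,SN
R_NAcc,SN
L_dlPFC,FPN
R_dlPFC,FPN
L_IPS,FPN
R_IPS,FPN
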