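truth,NSR,LBBB,RBBB,APC,PVC
NSR,4794,81,33,29,63
LBBB,26,1968,2,0,4
RBBB,25,3,1363,5,4
APC,62,14,15,489,20
PVC,19,4,1,4,1172
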