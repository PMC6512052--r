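truth,NSR,LBBB,RBBB,APC,PVC
NSR,4788,51,39,66,56
LBBB,19,1973,3,3,2
RBBB,21,2,1371,5,1
APC,41,3,6,541,9
PVC,10,6,1,14,1169
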