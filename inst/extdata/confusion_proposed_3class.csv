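truth,NSR,APC,PVC
NSR,4794,29,63
APC,62,489,20
PVC,19,4,1172
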