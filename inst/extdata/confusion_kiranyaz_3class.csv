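truth,NSR,APC,PVC
NSR,73539,824,368
APC,837,1568,178
PVC,230,72,5277
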