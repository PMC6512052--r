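truth,NSR,APC,PVC
NSR,41873,300,947
APC,1520,282,9
PVC,1240,13,1943
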