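0.60268,0
0.00732,0.98
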