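0.75,0,0,0,0
0.0749999999999999,0.208645738078595,0,0,0
0,0.70614484271562,0.218262322039492,0,0
0,0,0.737927600837164,0.601022725516484,0
0,0,0,0.34484338126935,0.913444153629243
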