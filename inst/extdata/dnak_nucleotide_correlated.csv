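subdomain,label,residue
I-A,D8,8
I-A,C15,15
I-A,D33,33
I-A,P37,37
I-A,S38,38
I-A,P143,143
I-A,A144,144
I-A,Y145,145
I-B,I39,39
I-B,G51,51
I-B,L66,66
I-B,A68,68
I-B,L72,72
II-A,D194,194
II-A,L195,195
II-A,F200,200
II-A,G223,223
II-A,T225,225
II-A,G228,228
II-A,G229,229
II-A,V230,230
II-A,L339,339
II-A,T344,344
II-A,M346,346
II-A,P347,347
II-A,V349,349
II-B,A265,265
II-B,K268,268
II-B,A269,269
II-B,S274,274
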