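subdomain,label,residue
I-A,N13,13
I-A,S14,14
I-A,D20,20
I-B,G51,51
I-B,P67,67
I-B,A68,68
I-B,I73,73
I-B,G74,74
I-B,Q83,83
I-B,R84,84
I-B,D85,85
I-B,E104,104
I-B,V105,105
II-A,K183,183
II-A,G184,184
II-A,T185,185
II-A,G186,186
II-A,L195,195
II-A,G198,198
II-A,T199,199
II-A,I202,202
II-A,S203,203
II-A,N222,222
II-A,G223,223
II-A,L227,227
II-A,G228,228
II-A,G229,229
II-A,V340,340
II-A,G341,341
II-A,G342,342
II-A,K363,363
II-B,V281,281
II-B,A288,288
II-B,D289,289
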