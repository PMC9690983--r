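from,AG,WL,GL,WT,UB,BC,RS,IM
AG,0.8652,0.0159,0.0060,0.0013,0.0218,0.0002,0.0159,0.0739
WL,0.0077,0.9720,0.0096,0.0004,0.0015,0.0000,0.0006,0.0082
GL,0.0083,0.0278,0.9457,0.0003,0.0014,0.0000,0.0015,0.0147
WT,0.0205,0.0081,0.0043,0.8838,0.0034,0.0525,0.0033,0.0243
UB,0.0124,0.0036,0.0054,0.0010,0.9705,0.0001,0.0019,0.0051
BC,0.0243,0.0010,0.0001,0.0047,0.0025,0.8565,0.0042,0.1068
RS,0.0386,0.0040,0.0018,0.0019,0.0535,0.0004,0.8801,0.0197
IM,0.0248,0.0138,0.0064,0.0063,0.0156,0.0009,0.0235,0.9087
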