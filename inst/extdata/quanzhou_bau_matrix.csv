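from,AG,WL,GL,WT,UB,BC,RS,IM
AG,0.8939,0.0164,0.0062,0.0013,0.0225,0.0002,0.0164,0.0431
WL,0.0077,0.9754,0.0096,0.0004,0.0015,0.0000,0.0006,0.0048
GL,0.0084,0.0280,0.9516,0.0003,0.0014,0.0000,0.0015,0.0086
WT,0.0207,0.0082,0.0043,0.8930,0.0034,0.0530,0.0033,0.0142
UB,0.0124,0.0036,0.0054,0.0010,0.9726,0.0001,0.0019,0.0030
BC,0.0255,0.0011,0.0001,0.0049,0.0026,0.8991,0.0044,0.0623
RS,0.0389,0.0040,0.0018,0.0019,0.0539,0.0004,0.8875,0.0115
IM,0.0248,0.0138,0.0064,0.0063,0.0156,0.0009,0.0235,0.9087
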