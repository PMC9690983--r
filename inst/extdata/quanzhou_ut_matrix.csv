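from,AG,WL,GL,WT,UB,BC,RS,IM
AG,0.8701,0.0160,0.0060,0.0013,0.0486,0.0002,0.0160,0.0420
WL,0.0077,0.9737,0.0096,0.0004,0.0032,0.0000,0.0006,0.0048
GL,0.0084,0.0280,0.9501,0.0003,0.0030,0.0000,0.0015,0.0086
WT,0.0206,0.0082,0.0043,0.8895,0.0073,0.0528,0.0033,0.0141
UB,0.0124,0.0036,0.0054,0.0010,0.9726,0.0001,0.0019,0.0030
BC,0.0254,0.0011,0.0001,0.0049,0.0056,0.8964,0.0044,0.0621
RS,0.0363,0.0037,0.0017,0.0018,0.1163,0.0004,0.8289,0.0107
IM,0.0243,0.0135,0.0063,0.0062,0.0337,0.0009,0.0231,0.8920
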