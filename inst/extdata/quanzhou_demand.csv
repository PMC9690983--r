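name,y2018,bau_2031,ip_2031,ut_2031
AG,246167.64,229085.55,221993.37,223121.52
WL,553564.17,549437.22,547411.14,548387.01
GL,158190.30,158029.47,157015.17,157703.85
WT,14150.07,13633.92,13515.57,13589.55
UB,45880.29,53397.09,53092.80,64036.44
BC,6286.14,6537.78,6232.05,6486.93
RS,34193.07,36587.79,36195.12,34428.42
IM,44488.89,56211.75,67436.28,55161.18
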