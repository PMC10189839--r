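name,resA,resB,rule,theme
Q61_D92,61,92,sidechain,switch2-helix-coupling
E62_H95,62,95,sidechain,switch2-helix-coupling
A11_Q61,11,61,sidechain,p-loop-switch2
G12_Q61,12,61,sidechain,p-loop-switch2
I36_A59,36,59,sidechain,switch1-switch2-coordination
Y32_Y40,32,40,sidechain,switch1-switch2-coordination
Y32_A59,32,59,sidechain,switch1-switch2-coordination
G12_T35,12,35,sidechain,nucleotide-mg-coordination
Q61_T35,61,35,sidechain,nucleotide-mg-coordination
S17_T35,17,35,sidechain,nucleotide-mg-coordination
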