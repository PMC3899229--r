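haplotype,state
W14,local_wolf
W16,nonlocal_wolf
W1,nonlocal_wolf
W2,nonlocal_wolf
W6,nonlocal_wolf
H6,nonlocal_wolf
H14,nonlocal_wolf
D01,dog
D05,dog
D06,dog
D08,dog
D09,dog
D10,dog
D13,dog
D14,dog
D15,dog
D16,dog
D17,dog
D18,dog
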