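haplotype,state
YH17,local_wolf
YH26,local_wolf
YH05,dog_shared
YH32,private
YH01,dog_shared
YH06,dog_shared
YH24,dog_shared
YH27,dog_shared
YH28,dog_shared
YH34,dog_shared
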