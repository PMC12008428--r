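cluster,n_eyes,rdme_yes,rdme_no,vision_poor_yes,vision_poor_no
1,122,72,50,70,52
2,45,31,14,27,18
3,32,19,13,21,11
4,35,12,23,10,25
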