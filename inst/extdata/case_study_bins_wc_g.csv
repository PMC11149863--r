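true_class,Mb,Zc,Mm,BWG,Md,Me,De spp,Gg,Ko spp,Pm & Boat,ES ping,No label
Mb,391,0,23,0,0,3,27,0,4,4,0,22
Zc,2,286,1,0,1,0,75,5,0,4,4,36
Mm,6,0,142,0,0,2,13,2,1,0,0,14
Mm | Me,0,0,8,0,0,0,2,0,0,0,0,2
No label,218,257,205,119,28,40,10749,1071,220,7246,272,711
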